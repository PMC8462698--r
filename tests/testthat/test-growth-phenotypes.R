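test_that("efficiency is the signed OD increment", {
  expect_equal(efficiency(0.1, 0.1), 0)
  expect_equal(efficiency(0.1, 0.72), 0.62)
  # linearity: scaling both ODs by c scales efficiency by c
  set.seed(1)
  oi <- runif(20); of <- runif(20)
  expect_equal(efficiency(3 * oi, 3 * of), 3 * efficiency(oi, of))
  tbl <- make_growth_tbl(list(a = c(0.5, -0.1)))
  expect_equal(efficiency(tbl)$efficiency, c(0.5, -0.1))
})

test_that("fit_logistic recovers noiseless parameters on the day grid", {
  t <- c(0, 4, 5, 7, 8, 9, 10, 11)
  od <- 1.2 / (1 + exp(-0.8 * (t - 5)))
  f <- fit_logistic(t, od)
  expect_true(f$converged)
  expect_lt(max(abs(c(f$K - 1.2, f$R - 0.8, f$x0 - 5))), 1e-6)
  expect_lt(f$residual_norm, 1e-8)
})

test_that("fit_logistic handles degenerate and bounded cases", {
  t <- c(0, 4, 5, 7, 8, 9, 10, 11)
  flat <- fit_logistic(t, rep(0.5, 8))
  expect_lt(abs(flat$R), 1e-6)
  expect_lt(flat$residual_norm, 1e-8)

  # truth outside bounds pins the parameter at the box edge
  big <- fit_logistic(t, 20 / (1 + exp(-0.8 * (t - 5))))
  expect_equal(big$K, 10)
  expect_true(big$boundary_active)

  expect_error(fit_logistic(c(0, 1, 2), c(1, 2, 3)), "insufficient data")
  expect_error(fit_logistic(t, rep(1, 3)), "lengths differ")
})

test_that("average_fit averages parameters over converged fits", {
  f1 <- fit_logistic(c(0,4,5,7,8,9,10,11),
                     1 / (1 + exp(-1 * (c(0,4,5,7,8,9,10,11) - 5))))
  expect_equal(average_fit(list(f1))[c("K","R","x0")],
               f1[c("K","R","x0")])

  mk <- function(K, R, x0) structure(
    list(K = K, R = R, x0 = x0, converged = TRUE, residual_norm = 0,
         boundary_active = FALSE), class = "logistic_fit")
  av <- average_fit(list(mk(1, 1, 5), mk(3, 3, 7)))
  expect_equal(c(av$K, av$R, av$x0), c(2, 2, 6))

  bad <- mk(1, 1, 1); bad$converged <- FALSE
  av2 <- average_fit(list(mk(1, 1, 5), mk(3, 3, 7), bad))
  expect_equal(attr(av2, "n_excluded"), 1)
  expect_error(average_fit(list(bad)), "no converged fits")
})

test_that("growth_rate returns per-replicate R and recovers generator order", {
  cfg <- synthetic_config(od_noise_sd = 0)
  strains <- panel_strains()[1:2, ]  # recipient (R=0.9) vs donor (R=0.45)
  tc <- generate_timecourses(cfg, strains, 4, seed = 5)
  r_rec <- growth_rate(tc[tc$strain_id == "recipient_wt", ])
  r_don <- growth_rate(tc[tc$strain_id == "donor_wt", ])
  # zero-noise replicates of one truth give identical R
  expect_lt(diff(range(r_rec)), 1e-8)
  expect_equal(unname(r_rec[1]), 0.9, tolerance = 1e-6)
  # the faster-growing strain has the larger mean R
  expect_gt(mean(r_rec), mean(r_don))
  expect_error(growth_rate(tc[0, ]), "empty")
})

test_that("quantify_viability follows the densest-countable-spot rule", {
  mk_v <- function(counts) {
    # counts: list per dilution exponent 1..5 of the two technical spots
    rows <- lapply(1:5, function(e) tibble::tibble(
      strain_id = "s", temperature_C = 39, replicate = "r1",
      dilution_exponent = e, tech_rep = c("t1", "t2"),
      colonies_or_LAWN = as.character(counts[[e]]),
      od_end = 2.0, spot_volume_ml = 0.003))
    dplyr::bind_rows(rows)
  }
  v <- mk_v(list(c("LAWN","LAWN"), c("LAWN","LAWN"), c(86, 86), c(9, 9),
                 c(1, 1)))
  est <- quantify_viability(v)
  expect_equal(est$selected_dilution, 3)
  expect_equal(est$cfu_per_ml, 86 / 0.003 / 1e-3)       # ~2.867e7
  expect_equal(est$cfu_per_ml_per_od, 86 / 0.003 / 1e-3 / 2)  # ~1.433e7

  # technical spots are averaged
  est2 <- quantify_viability(mk_v(list(c(40, 60), c(4, 6), c(0, 1),
                                       c(0, 0), c(0, 0))))
  expect_equal(est2$selected_dilution, 1)
  expect_equal(est2$cfu_per_ml, 50 / 0.003 / 1e-1)

  # a dilution is usable only if EVERY technical spot is countable
  est3 <- quantify_viability(mk_v(list(c("LAWN", 90), c(10, 11), c(1, 1),
                                       c(0, 0), c(0, 0))))
  expect_equal(est3$selected_dilution, 2)

  all_lawn <- quantify_viability(mk_v(replicate(5, c("LAWN","LAWN"),
                                                simplify = FALSE)))
  expect_true(all_lawn$censored_above)
  expect_true(is.na(all_lawn$cfu_per_ml))

  zero <- quantify_viability(mk_v(replicate(5, c(0, 0), simplify = FALSE)))
  expect_equal(zero$cfu_per_ml, 0)
  expect_true(zero$below_detection)

  # row order invariance
  shuf <- v[sample(nrow(v)), ]
  expect_equal(quantify_viability(shuf)$cfu_per_ml, est$cfu_per_ml)
})
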