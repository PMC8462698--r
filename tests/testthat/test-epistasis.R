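test_that("bootstrap_effect resamples both groups with replacement", {
  # zero-variance groups: every iterate is the constant difference
  tbl <- make_growth_tbl(list(f = rep(0.5, 4), r = rep(0.2, 4)))
  b <- bootstrap_effect(tbl, "f", "r", 39, n_boot = 50, seed = 1)
  expect_equal(b, rep(0.3, 50))

  # seeded determinism
  tbl2 <- make_growth_tbl(list(f = c(0.4, 0.5, 0.7), r = c(0.1, 0.2, 0.25)))
  expect_identical(bootstrap_effect(tbl2, "f", "r", 39, 500, seed = 3),
                   bootstrap_effect(tbl2, "f", "r", 39, 500, seed = 3))

  # Monte Carlo consistency: boot mean near the point estimate
  b2 <- bootstrap_effect(tbl2, "f", "r", 39, 5000, seed = 4)
  pt <- marginal_effect(tbl2, "f", "r", 39)$effect
  expect_lt(abs(mean(b2) - pt), 3 * sd(b2) / sqrt(5000))

  one <- make_growth_tbl(list(f = 0.4, r = c(0.1, 0.2)))
  expect_warning(bootstrap_effect(one, "f", "r", 39, 10, seed = 1),
                 "single replicate")
})

test_that("additive expectation sums means and iterates", {
  tbl <- make_growth_tbl(list(s1 = c(0.24, 0.26), s2 = c(0.3, 0.32),
                              r = c(0.2, 0.21)))
  e1 <- marginal_effect(tbl, "s1", "r", 39, n_boot = 400, seed = 5)
  e2 <- marginal_effect(tbl, "s2", "r", 39, n_boot = 400, seed = 6)
  ae <- additive_expectation(list(e1, e2))
  expect_equal(ae$expected, e1$effect + e2$effect)
  expect_equal(ae$boot, e1$boot + e2$boot)

  zero <- make_growth_tbl(list(s = rep(0.2, 3), r = rep(0.2, 3)))
  ez <- marginal_effect(zero, "s", "r", 39, n_boot = 100, seed = 1)
  expect_equal(additive_expectation(list(ez, ez))$expected, 0)

  eights <- replicate(8, make_est(0.05, rnorm(100)), simplify = FALSE)
  expect_equal(additive_expectation(eights)$expected, 0.4)

  short <- make_est(0.05, rnorm(50))
  expect_error(additive_expectation(list(eights[[1]], short)),
               "mismatched bootstrap lengths")
})

test_that("independently bootstrapped locus effects have additive variance", {
  set.seed(8)
  tbl <- make_growth_tbl(list(
    s1 = rnorm(8, 0.3, 0.05), s2 = rnorm(8, 0.35, 0.05),
    s3 = rnorm(8, 0.4, 0.05), r = rnorm(8, 0.2, 0.05)))
  fx <- lapply(c("s1", "s2", "s3"), function(s, seed = match(s, c("s1","s2","s3")))
    marginal_effect(tbl, s, "r", 39, n_boot = 20000, seed = 100 + seed))
  ae <- additive_expectation(fx)
  v_sum <- var(ae$boot)
  v_parts <- sum(vapply(fx, function(e) var(e$boot), numeric(1)))
  expect_lt(abs(v_sum - v_parts) / v_parts, 0.05)
})

test_that("epistasis_test computes epsilon and the smoothed tail p", {
  # identical observed and expected bootstrap: epsilon 0, label none
  b <- rnorm(500)
  obs <- make_est(0.4, 0.4 + b)
  exp_ <- structure(list(expected = 0.4, boot = 0.4 + b),
                    class = "additive_expectation")
  r <- epistasis_test(obs, exp_, "less")
  expect_equal(r$epsilon, 0)
  expect_equal(r$label, "none")
  expect_equal(r$p_value, 1)  # all differences are exactly 0 (>= 0)

  # zero-noise additive panel: epsilon exactly 0, p at maximum
  loci <- panel_loci()
  cfg <- synthetic_config(loci = loci, noise_sd = 0,
                          interaction = list(type = "additive"))
  strains <- panel_strains(loci)
  g <- generate_growth_panel(cfg, strains, 39, seed = 2)
  singles <- setNames(paste0("single_", loci$name), loci$name)
  ea <- epistasis_analysis(g, "stack_8", singles, "recipient_wt", 39,
                           n_boot = 200, seed = 3)
  expect_equal(ea$result$epsilon, 0, tolerance = 1e-12)
  expect_equal(ea$result$p_value, 1)
  expect_equal(ea$result$label, "none")

  # two-sided doubles the smaller tail, capped at 1
  r2 <- epistasis_test(obs, exp_, "two_sided")
  expect_equal(r2$p_value, 1)
  expect_warning(epistasis_test(make_est(0.1, rnorm(50)),
                                structure(list(expected = 0.2,
                                               boot = rnorm(50)),
                                          class = "additive_expectation"),
                                "less"),
                 "n_boot < 100")
})

test_that("smoothed p is bounded away from 0 and capped at 1", {
  set.seed(13)
  for (i in 1:20) {
    obs <- make_est(rnorm(1), rnorm(300, mean = rnorm(1)))
    exp_ <- structure(list(expected = 0, boot = rnorm(300)),
                      class = "additive_expectation")
    for (alt in c("less", "two_sided")) {
      p <- epistasis_test(obs, exp_, alt)$p_value
      expect_gt(p, 0)
      expect_lte(p, 1)
      expect_gte(p, 1 / 301)
    }
  }
})

test_that("locus interaction classification follows the CI definitions", {
  set.seed(21)
  narrow <- function(m) rnorm(4000, m, 0.02)
  # masking: detectable alone, indistinguishable from zero in combination
  expect_equal(classify_locus_interaction(make_est(0.10, narrow(0.10)),
                                          make_est(0.005, narrow(0.005))),
               "masking")
  # sign: both exclude zero with opposite signs
  expect_equal(classify_locus_interaction(make_est(0.10, narrow(0.10)),
                                          make_est(-0.10, narrow(-0.10))),
               "sign")
  # magnitude: both positive, combination significantly smaller
  expect_equal(classify_locus_interaction(make_est(0.20, narrow(0.20)),
                                          make_est(0.10, narrow(0.10))),
               "negative_magnitude")
  expect_equal(classify_locus_interaction(make_est(0.10, narrow(0.10)),
                                          make_est(0.20, narrow(0.20))),
               "positive_magnitude")
  # nothing distinguishable alone: none
  expect_equal(classify_locus_interaction(make_est(0.01, narrow(0.01)),
                                          make_est(0.01, narrow(0.01))),
               "none")
  expect_error(classify_locus_interaction(make_est(0.1, NULL),
                                          make_est(0.1, narrow(0.1))),
               "bootstrap")
})

test_that("trend binomial test matches the closed-form tail", {
  mk_path <- function(signs) lapply(signs, function(s) make_est(s, rnorm(10)))
  r <- trend_binomial_test(mk_path(c(rep(1, 7), -1)))
  expect_equal(r$n_positive, 7)
  expect_equal(r$p_value, 9 / 256)   # printed as ~0.03
  expect_equal(trend_binomial_test(mk_path(rep(1, 8)))$p_value, 1 / 256)
  expect_equal(trend_binomial_test(mk_path(c(rep(1, 4), rep(-1, 4))))$p_value,
               163 / 256)
  expect_error(trend_binomial_test(list()), "at least one")
  expect_error(trend_binomial_test(mk_path(1), "significant_positive"),
               "intervals")
})
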