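test_that("true_phenotype implements the interaction regimes", {
  loci <- panel_loci()
  cfg_add <- synthetic_config(loci = loci, baseline_efficiency = 0.2,
                              per_locus_effects = setNames(rep(0.05, 8),
                                                           loci$name),
                              interaction = list(type = "additive"))
  expect_equal(true_phenotype(cfg_add, "00000000"), 0.2)
  expect_equal(true_phenotype(cfg_add, "11111111"), 0.6)
  expect_equal(true_phenotype(cfg_add, "recipient_wt"), 0.2)

  # magnitude damping: k-th added locus contributes effect * f^(k-1)
  cfg_dmp <- synthetic_config(loci = loci, baseline_efficiency = 0.2,
                              per_locus_effects = setNames(rep(0.05, 8),
                                                           loci$name),
                              interaction = list(type = "magnitude_damping",
                                                 factor = 0.5))
  expect_equal(true_phenotype(cfg_dmp, "11000000"),
               0.2 + 0.05 + 0.05 * 0.5)

  # masking: target contributes nothing when a masker allele is present
  cfg_msk <- synthetic_config(loci = loci,
                              interaction = list(type = "masking",
                                                 target = "SCC2",
                                                 maskers = c("DYN1", "MYO1")))
  with_target <- true_phenotype(cfg_msk, "11100000")  # DYN1+MYO1+SCC2
  without_target <- true_phenotype(cfg_msk, "11000000")
  expect_equal(with_target, without_target)
  # alone the target still acts
  expect_gt(true_phenotype(cfg_msk, "00100000"),
            true_phenotype(cfg_msk, "00000000"))

  # sign: target's effect is negated in context
  cfg_sgn <- synthetic_config(loci = loci,
                              interaction = list(type = "sign",
                                                 target = "SCC2",
                                                 context = "DYN1"))
  e <- cfg_sgn$per_locus_effects[["SCC2"]]
  expect_equal(true_phenotype(cfg_sgn, "10100000") -
                 true_phenotype(cfg_sgn, "10000000"), -e)

  expect_error(synthetic_config(interaction = list(type = "quadratic")),
               "unknown interaction regime")
})

test_that("damping factor solves the joint/additive fraction", {
  f <- damping_factor_for_fraction(0.6, 8)
  expect_equal((1 - f^8) / (8 * (1 - f)), 0.6, tolerance = 1e-9)
  expect_equal(damping_factor_for_fraction(1, 8), 1)
})

test_that("growth panel generation is exact at zero noise and seeded", {
  loci <- panel_loci()
  cfg <- synthetic_config(loci = loci, noise_sd = 0)
  strains <- panel_strains(loci)[1:5, ]
  g <- generate_growth_panel(cfg, strains, 39, seed = 2)
  for (s in strains$strain_id) {
    truth <- true_phenotype(cfg, strains$genotype[strains$strain_id == s])
    expect_equal(strain_efficiencies(g, s, 39), rep(truth, 8))
  }
  expect_equal(g$od_initial, rep(0.1, nrow(g)))

  cfg2 <- synthetic_config(loci = loci, noise_sd = 0.05)
  a <- generate_growth_panel(cfg2, strains, 39, seed = 9)
  b <- generate_growth_panel(cfg2, strains, 39, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, generate_growth_panel(cfg2, strains, 39,
                                                  seed = 10)))
  expect_error(synthetic_config(replicates_per_day = 1), "2..8")
})

test_that("generator sample mean matches truth at CLT precision", {
  loci <- panel_loci()
  cfg <- synthetic_config(loci = loci, noise_sd = 0.05,
                          replicates_per_day = 8L, n_days = 1250L)
  strains <- panel_strains(loci)[3, ]  # one single-swap strain
  g <- generate_growth_panel(cfg, strains, 39, seed = 77)
  vals <- strain_efficiencies(g, strains$strain_id, 39)
  expect_equal(length(vals), 10000)
  truth <- true_phenotype(cfg, strains$genotype)
  expect_lt(abs(mean(vals) - truth), 3 * 0.05 / sqrt(10000))
})

test_that("timecourse generation hits the logistic curve", {
  cfg <- synthetic_config(od_noise_sd = 0)
  strains <- panel_strains()[1:2, ]
  tc <- generate_timecourses(cfg, strains, 4, seed = 3)
  lt <- cfg$logistic_truth
  sub <- tc[tc$strain_id == "recipient_wt" & tc$replicate == "r1", ]
  p <- lt[lt$strain_id == "recipient_wt", ]
  expect_equal(sub$od, p$K / (1 + exp(-p$R * (sub$day - p$x0))),
               tolerance = 1e-12)
  expect_equal(sub$day, c(0, 4, 5, 7, 8, 9, 10, 11))

  # R = 0 degenerates to a flat series at K/2
  cfg$logistic_truth <- tibble::tibble(strain_id = "recipient_wt",
                                       K = 1.4, R = 0, x0 = 5)
  flat <- generate_timecourses(cfg, panel_strains()[1, ], 4, seed = 3)
  expect_equal(flat$od, rep(0.7, nrow(flat)))

  expect_error(generate_timecourses(cfg, panel_strains()[1:3, ], 4),
               "logistic_truth missing")
})

test_that("viability generation censors lawns and respects zero truth", {
  loci <- panel_loci()
  cfg <- synthetic_config(loci = loci)
  cfg$cfu_truth <- c(recipient_wt = 0)
  v0 <- generate_viability(cfg, panel_strains(loci)[1, ], 39, seed = 4)
  expect_true(all(v0$colonies_or_LAWN == "0"))

  # expected 500 colonies at the densest dilution with threshold 100 -> LAWN
  cfg$cfu_truth <- c(recipient_wt = 500 / 0.003 / 1e-1)
  v <- generate_viability(cfg, panel_strains(loci)[1, ], 39, seed = 4)
  dense <- v[v$dilution_exponent == 1, ]
  expect_true(all(dense$colonies_or_LAWN == "LAWN"))

  expect_identical(generate_viability(cfg, panel_strains(loci)[1, ], 39,
                                      seed = 8),
                   generate_viability(cfg, panel_strains(loci)[1, ], 39,
                                      seed = 8))
})
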