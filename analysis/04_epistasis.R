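#!/usr/bin/env Rscript
# Additive-expectation epistasis analysis: bootstrap the observed joint
# effect of the full swap and the sum of the eight single-locus effects
# (one shared wild-type resample per iterate), test epsilon, classify each
# locus's interaction from its effect alone vs in combination, and run the
# path-trend binomial test.
#
# Usage: Rscript analysis/04_epistasis.R [seed]

suppressPackageStartupMessages(library(thermoswap))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

loci <- panel_loci()
strains <- panel_strains(loci)
growth <- read_measurements("results/data/growth_39C.csv", "growth")
singles <- setNames(paste0("single_", loci$name), loci$name)

ea <- epistasis_analysis(growth, "stack_8", singles, "recipient_wt", 39,
                         n_boot = 10000L, alternative = "less",
                         seed = seed + 1000L)
res <- ea$result
cat(sprintf("observed joint effect:  %+.4f dOD\n", res$observed_joint))
cat(sprintf("additive expectation:   %+.4f dOD\n", res$expected_additive))
cat(sprintf("epsilon:                %+.4f (bootstrap p = %.4g) -> %s\n",
            res$epsilon, res$p_value, res$label))
write_results(tibble::tibble(
  observed_joint = res$observed_joint,
  expected_additive = res$expected_additive,
  epsilon = res$epsilon, p_value = res$p_value, label = res$label,
  n_boot = length(res$boot_observed)), "results/epistasis_39C.csv")

path_fx <- path_effects(growth, path_strain_ids(strains), 39, loci,
                        n_boot = 10000L, seed = seed + 100L)
labels <- vapply(loci$name, function(lc) {
  step <- Filter(function(e) e$locus == lc, path_fx)[[1]]
  classify_locus_interaction(ea$single_effects[[lc]], step)
}, character(1))
write_results(tibble::tibble(locus = names(labels), label = labels),
              "results/locus_interactions_39C.csv")
cat("per-locus interaction labels:\n")
for (lc in names(labels)) cat(sprintf("  %-6s %s\n", lc, labels[[lc]]))

trend <- trend_binomial_test(path_fx)
cat(sprintf("path trend: %d of %d steps beneficial, exact binomial p = %.4g\n",
            trend$n_positive, trend$n_steps, trend$p_value))
write_results(tibble::tibble(n_steps = trend$n_steps,
                             n_positive = trend$n_positive,
                             p_value = trend$p_value),
              "results/path_trend_39C.csv")
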