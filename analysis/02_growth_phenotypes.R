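#!/usr/bin/env Rscript
# Convert the raw measurements into the three phenotype readouts:
# growth efficiency (dOD over the incubation), per-replicate logistic fits
# (K, R, x0) with the average fit per strain, and CFU/mL/OD viability.
#
# Usage: Rscript analysis/02_growth_phenotypes.R   (after 01_simulate.R)

suppressPackageStartupMessages(library(thermoswap))

growth <- read_measurements("results/data/growth_39C.csv", "growth")
eff <- efficiency(growth)
write_results(eff, "results/growth_efficiency_39C.csv")
cat(sprintf("efficiency: %d replicate cultures across %d strains\n",
            nrow(eff), length(unique(eff$strain_id))))

tc <- read_measurements("results/data/timecourse_4C.csv", "timecourse")
fit_rows <- list()
for (s in unique(tc$strain_id)) {
  sub <- tc[tc$strain_id == s, ]
  fits <- lapply(split(sub, sub$replicate), function(d) {
    d <- d[order(d$day), ]
    fit_logistic(d$day, d$od)
  })
  av <- average_fit(fits)
  rates <- growth_rate(sub)
  fit_rows[[s]] <- tibble::tibble(
    strain_id = s, K = av$K, R = av$R, x0 = av$x0,
    n_replicates = length(fits),
    n_excluded = attr(av, "n_excluded"),
    mean_rate = mean(rates))
  cat(sprintf("%-14s average fit: K=%.3f R=%.3f x0=%.2f (%d replicates)\n",
              s, av$K, av$R, av$x0, length(fits)))
}
write_results(dplyr::bind_rows(fit_rows), "results/logistic_fits_4C.csv")

vb <- read_measurements("results/data/viability_39C.csv", "viability")
vt <- viability_table(vb, lawn_threshold = 100)
write_results(vt, "results/viability_39C.csv")
for (s in unique(vt$strain_id)) {
  cat(sprintf("%-14s viability: %.3g CFU/mL/OD\n", s,
              mean(vt$cfu_per_ml_per_od[vt$strain_id == s], na.rm = TRUE)))
}
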