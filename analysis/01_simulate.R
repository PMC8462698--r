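#!/usr/bin/env Rscript
# Simulate the combinatorial allele-swap panel in its stated world: the
# eight-locus strain series (wild-types, single swaps, cumulative stacks),
# replicate growth efficiencies at the hot assay temperature, cold-growth
# OD timecourses, and dilution-series viability counts.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressPackageStartupMessages(library(thermoswap))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
loci <- panel_loci()
syn <- synthetic_config(loci = loci, seed = seed)
strains <- panel_strains(loci)

growth <- generate_growth_panel(syn, strains, temperature = 39,
                                seed = seed)
write_measurements(growth, "results/data/growth_39C.csv", "growth")

tc_strains <- strains[strains$strain_id %in% syn$logistic_truth$strain_id, ]
tc <- generate_timecourses(syn, tc_strains, temperature = 4,
                           seed = seed + 1L)
write_measurements(tc, "results/data/timecourse_4C.csv", "timecourse")

vb_strains <- strains[strains$strain_id %in% names(syn$cfu_truth), ]
vb <- generate_viability(syn, vb_strains, temperature = 39,
                         seed = seed + 2L)
write_measurements(vb, "results/data/viability_39C.csv", "viability")

cat(sprintf("simulated %d strains: %d growth rows, %d timecourse rows, %d viability rows\n",
            nrow(strains), nrow(growth), nrow(tc), nrow(vb)))
cat(sprintf("ground truth: baseline %.3f dOD, per-locus effects %.3f dOD, damping factor %.4f\n",
            syn$baseline_efficiency, syn$per_locus_effects[[1]],
            syn$interaction$factor))
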