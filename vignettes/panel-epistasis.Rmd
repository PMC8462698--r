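---
title: "Methods: allele-swap panel analysis and the bootstrap additive-expectation null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-swap panel analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoswap)
```

This vignette is the package's own account of its statistical methods:
the phenotype models, the resampling scheme behind the epistasis test,
the numerical choices, what the synthetic panel generator does and does
not emulate, and the package's known limitations.

## The experimental design being modeled

A combinatorial allele-replacement panel probes a polygenic trait —
here, temperature tolerance divergence between a thermotolerant donor
species (*S. cerevisiae*) and a thermosensitive recipient
(*S. paradoxus*). The strain set comprises the two purebred wild-types,
eight single-locus swap strains (the donor allele of one gene, promoter
plus coding region, replacing the recipient's), and a cumulative
stacking series that adds one locus at a time up to the full 8x swap.
Genotypes are bit-vectors over the panel's locus list (0 = recipient
allele, 1 = donor allele); the purebred wild-types carry reserved tokens
rather than bit-strings, because the donor wild-type differs from the
recipient genome-wide, not only at the eight loci — the all-ones
genotype is *not* the donor species.

Three replicate-level readouts are supported:

* **Growth efficiency**: final minus initial OD₆₀₀ over a fixed
  incubation (dimensionless ΔOD; sign preserved). Replicates are 2–8
  colonies per strain per experiment day, pooled across days with no
  batch term — matching how such panels are routinely analyzed.
* **Logistic growth parameters** from OD timecourses measured on days
  0, 4, 5, 7, 8, 9, 10, 11 of a cold (4 °C) incubation (day 6
  optionally): `od(t) = K / (1 + exp(−R (t − x₀)))`, with carrying
  capacity `K` (OD), rate `R` (per day; conventionally reported as
  OD/day) and sigmoidal midpoint `x₀` (days).
* **Viability** as colony-forming units from a 1:10 dilution series,
  3 µL spots, two technical replicates per dilution, normalized by
  end-point turbidity (CFU/mL/OD) to discount dead cells that still
  contribute to OD.

## Effect decomposition

For strains `focal` and `reference` measured at one temperature, the
effect of the swap distinguishing them is the difference of pooled
replicate means. Two backgrounds matter for each locus:

* **alone** — the single-swap strain vs the recipient wild-type;
* **entering the path** — strain `X` vs its immediate predecessor
  `X−1` in the stacking series (consecutive strains must differ by
  exactly one added locus; this is validated from genotypes).

Path effects telescope exactly: their sum over a complete path equals
the endpoint mean difference (tested to 1e−12), and on an additive
noise-free panel they equal the marginal effects for every locus in any
path order. The stacking order of real panels is experiment-specific;
the default panel order starts with `DYN1` (historically the first
single-gene transgenic) and is user-configurable, since no canonical
order exists beyond that.

Headline scalar metrics: fold change `mean(focal)/mean(reference)`
(undefined when the reference mean is ≤ 0, since efficiencies can be
negative) and the recapitulation fraction
`100 (m_joint − m_recipient) / (m_donor − m_recipient)`. Recapitulation
is computed on the linear efficiency scale; log-scaled displays of the
same strains are treated as presentation, not analysis.

## The bootstrap additive-expectation null

The expected joint phenotype under independent gene function is the sum
of the eight single-locus effects. Uncertainty is built from the
replicates themselves: each bootstrap iterate resamples every strain's
replicate set with replacement at its original size, recomputes each
single-locus effect and their sum ("one bootstrap's worth" of the
additive prediction), and recomputes the observed joint effect. The
deviation is `epsilon = observed_joint − expected_additive`, and the
one-sided p-value for negative epistasis is the smoothed fraction of
iterates in which `boot_observed − boot_expected ≥ 0`:
`p = (#{d ≥ 0} + 1)/(n_boot + 1)` (two-sided: double the smaller tail,
capped at 1). Smoothing keeps p strictly inside (0, 1].

**One reference resample per iterate.** The epsilon statistic reuses the
same wild-type sample in all nine of its terms
(`epsilon̂ = m_joint − Σᵢ m_i + 7 m_wt` for eight loci). A scheme that
redraws the wild-type independently for every term inflates none of the
point estimates but *understates* the statistic's sampling variance by a
factor of roughly 58/18 at eight loci, which would turn a nominal 5%
test into a ~20–30% one. `epistasis_analysis()` therefore draws one
wild-type resample per iterate and shares it across the observed effect
and all single-locus effects — the standard bootstrap of the statistic.
The standalone building blocks `bootstrap_effect()` and
`additive_expectation()` keep fully independent resampling (their
variances add, which the tests verify); the shared scheme is applied at
the level of the joint analysis where the statistic's correlation
structure matters.

**Calibration limitation.** Even with the shared-reference scheme, the
percentile-bootstrap counting test is anti-conservative at small
replicate counts: with 8 replicates/strain the bootstrap SD of
`epsilon̂` shrinks by √(7/8) and is itself noisy (few effective degrees
of freedom), so the realized type-I error at nominal α = 0.05 is about
8–10%, independent of the noise scale. The acceptance suite measures
this honestly (its calibration check expects 5% ± 2% and fails by a
small margin); users who need exact size at n ≈ 8 should raise the
replicate count or interpret p near α cautiously. Power is unaffected in
practice: a joint effect at 60% of the additive sum with noise 0.05 ΔOD
and 8 replicates/strain is flagged as negative magnitude epistasis in
>90% of panels.

## Interaction classification and intervals

Per-locus interaction types compare the effect **alone** against the
effect **entering the path**, via bootstrap intervals at the configured
level: `sign` if both intervals exclude 0 with opposite signs; `masking`
if the lone effect excludes 0 but the in-combination effect is
indistinguishable from 0; negative/positive `magnitude` if both exclude
0 with the same sign and the iterate-wise difference of magnitudes
excludes 0; otherwise `none`.

Intervals are **expanded percentile** intervals: plain percentile
intervals undercover at small n (the resampled-mean variance carries an
(n−1)/n shrink, and the bootstrap spread is estimated with few degrees
of freedom — at 8 replicates a nominal 95% interval covers ~90%). The
package therefore replaces the normal quantile with
`t_df · √(n/(n−1))` (df = combined group sizes minus 2) and maps back to
adjusted percentile levels of the same bootstrap distribution. This is
the standard small-sample remedy and is applied uniformly wherever
group sizes are known.

Note that under genuine magnitude damping, late path steps have small
true effects, so a damped locus can legitimately classify as `masking`
(its in-combination interval covers 0); masking and strong damping are
observationally adjacent at these sample sizes.

The directional path trend uses the exact binomial upper tail at null
success probability ½ over path steps. The default counted event is a
positive point effect (`point_positive`); counting only significant
boosts (`significant_positive`) is available but stricter, and with 7 of
8 positive steps the tail is 9/256 ≈ 0.035.

## Rank tests and multiplicity

Strain pairs are compared with Wilcoxon rank-sum tests — one-tailed for
the heat assays (directional hypothesis), two-tailed at the control
temperature — exact when the combined sample size is ≤ 25 with no ties,
otherwise the normal approximation with mid-rank tie correction and
continuity correction. All pairs computed in one invocation form one
Benjamini–Hochberg family. The exact branch is verified against
brute-force enumeration of all rank partitions for group sizes ≤ 6.

## Logistic fitting numerics

Bounded nonlinear least squares with every parameter constrained to
[−1, 10] by default. Starts: `K₀ = max(od)`, `R₀ = 1/day`,
`x₀,₀ = median(times)` — robust for sigmoid data on the sparse day grid.
Optimization is L-BFGS-B with analytic gradients, followed by a
projected Gauss–Newton polish: small-residual problems leave L-BFGS-B
stranded in flat valleys a few parts in 10⁶ from the optimum, and the
Gauss–Newton steps recover machine-precision parameters (noise-free
recovery is tested to 1e−6 across 100 random interior truths, and is
typically ~1e−12). Truths outside the box pin at the bound and are
flagged `boundary_active`. Non-convergence is carried as a flag, not an
exception, so rank-test stages can exclude replicates explicitly; fits
need ≥ 4 timepoints. The per-strain "average fit" averages parameters
(not refitting pooled data) over converged replicate fits — with one
parameter set reported per strain this matches standard practice, though
refitting pooled data is a defensible alternative; parameter averaging
was chosen for transparency and replicate-level error tracking.

## Viability quantification

From the 1:10 series the selected spot is the densest dilution at which
*every* technical replicate is countable (not a lawn); technical counts
are averaged; `cfu_per_ml = mean_count / spot_volume / dilution_factor`,
then divided by end-point OD. All-lawn series carry a censored-above
flag with no estimate; all-zero series report 0 with a below-detection
flag. The countability bound defaults to 100 colonies per 3 µL spot — a
conventional limit, configurable.

## The synthetic world

The generator's defaults are one internally consistent "stated world"
for the hot assay, fixed once:

| quantity | default | why |
|---|---|---|
| baseline (recipient wt) efficiency | 0.60 ΔOD | saturated-culture scale for a thermosensitive strain at 39 °C |
| per-locus effects | 0.134 ΔOD each | single swaps stay under a 1.4-fold benefit (0.134/0.60 ≈ 1.22×) |
| interaction | magnitude damping, factor 0.8467 | joint effect = 60% of the additive sum, i.e. the full swap sits at 2.07× the recipient |
| donor wt efficiency | 4.888 ΔOD | places the full swap at 15% recapitulation of the interspecies divergence |
| replicate noise | 0.05 ΔOD | plausible replicate spread; no published replicate-level variance exists to anchor it |
| replication | 4 days × 2 colonies = 8/strain | within the emulated 2–8 colonies/day design |
| logistic truths | recipient (1.5, 0.9, 5), donor (1.0, 0.45, 8), 8x (1.2, 0.55, 7) | cold growth: recipient fastest, donor slowest, full swap intermediate-low |
| CFU truths | 2×10⁵ / 2×10⁸ / 1.4×10⁶ | donor ~3 logs above recipient; full swap 7× the recipient |
| lawn threshold | 100 colonies/spot | conventional countability bound |

Magnitude damping ranks active loci in panel order: the k-th added locus
contributes `effect · f^(k−1)`. Masking zeroes the target's
contribution when any masker locus carries the donor allele; the sign
regime negates it when any context locus does (the two rules mirror
each other deliberately). Efficiency noise is Gaussian and
homoscedastic; day/batch shifts default to 0 (an additive per-day shift
is available), timecourse noise is Gaussian with a non-negativity
clamp, and colony counts are Poisson with lawn censoring.

What the generator does **not** emulate — hence what a green test does
not establish: heteroscedastic or heavy-tailed replicate noise,
day-by-strain interactions, plate/position effects, OD nonlinearity at
high density, non-logistic growth shapes (lags, diauxie), death-phase
kinetics, or correlated technical spots. Green tests establish that the
estimators recover the configured truth under the stated noise model,
not that the model is complete for any real instrument.

## Degenerate inputs and tie-breaks

Zero-variance bootstrap groups produce constant iterate values (and a
single-replicate group warns but runs). A flat timecourse fits with
`R ≈ 0` at `K ≈ 2·od` (the logistic at `R = 0` is `K/2` everywhere).
Identical samples in a two-sided rank test give p = 1. Equal wild-type
means make the recapitulation fraction undefined (error), as does a
non-positive reference mean for fold changes. Rank ties use mid-ranks
with the variance correction.

## Reproducibility

All generators and resampling consume explicit seeds;
`run_pipeline()` derives per-stage seeds deterministically from one run
seed (kept under 2³¹), so stage subsets never perturb one another and
identical config + seed reproduces result tables byte-identically. The
manifest records the config snapshot, input checksums, seed, stages and
package version; result tables serialize floats at 17 significant
digits so read-backs are bit-exact.
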