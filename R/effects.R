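# Per-locus allele effects against stated backgrounds, path-wise effect
# decomposition along the gene-stacking series, fold-change and
# trait-recapitulation metrics, and the rank-test / multiplicity inference.

#' Pooled efficiency values for one strain at one temperature
#'
#' Replicates are pooled across days, following the collation of all
#' replicate cultures across all experiment days.
#'
#' @param tbl growth table
#' @param strain strain id
#' @param temperature assay temperature
#' @return numeric vector of efficiencies
#' @export
strain_efficiencies <- function(tbl, strain, temperature) {
  sub <- tbl[tbl$strain_id == strain & tbl$temperature_C == temperature, ]
  if (!nrow(sub)) {
    stop("no measurements for strain '", strain, "' at ", temperature, "C")
  }
  sub$od_final - sub$od_initial
}

new_effect_estimate <- function(locus, background, effect, n_focal, n_ref,
                                boot = NULL, ci = NULL, ci_level = NA_real_) {
  structure(list(locus = locus, background = background, effect = effect,
                 n_focal = n_focal, n_ref = n_ref, boot = boot, ci = ci,
                 ci_level = ci_level),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("effect_estimate: %s | effect=%.4g", x$locus, x$effect))
  if (!is.null(x$ci)) {
    cat(sprintf(" [%.4g, %.4g] (%d boot)", x$ci[1], x$ci[2], length(x$boot)))
  }
  cat("\n")
  invisible(x)
}

# Bootstrap percentile interval.  When the group sizes are supplied, the
# expanded percentile adjustment is applied: plain percentile intervals
# undercover for small replicate counts because the resampled-mean variance
# shrinks by (n-1)/n and the spread is estimated with few degrees of
# freedom, so the nominal z quantile is replaced by
# t_{df} * sqrt(n / (n - 1)) and mapped back to adjusted percentile levels.
boot_ci <- function(boot, ci_level, n_groups = NULL) {
  a <- (1 - ci_level) / 2
  if (!is.null(n_groups) && all(n_groups > 1)) {
    df <- sum(n_groups) - length(n_groups)
    expand <- sqrt(mean(n_groups / (n_groups - 1)))
    a <- stats::pnorm(stats::qt(a, df) * expand)
  }
  unname(stats::quantile(boot, c(a, 1 - a), type = 7))
}

#' Marginal effect of an allele swap in a stated background
#'
#' The mean growth efficiency of the focal strain minus that of the
#' reference strain, replicates pooled across days.  With `n_boot > 0` a
#' bootstrap distribution and percentile interval are attached (see
#' [bootstrap_effect()]).
#'
#' @param tbl growth table
#' @param focal,reference strain ids
#' @param temperature assay temperature
#' @param locus label for the locus the difference is attributed to
#' @param n_boot bootstrap iterations (0 = point estimate only)
#' @param ci_level percentile-interval level
#' @param seed RNG seed for the bootstrap
#' @param ref_boot_means optional precomputed reference bootstrap means (one
#'   per iterate), to share one reference resample across several effects
#' @return `effect_estimate`
#' @export
marginal_effect <- function(tbl, focal, reference, temperature,
                            locus = focal, n_boot = 0, ci_level = 0.95,
                            seed = NULL, ref_boot_means = NULL) {
  xf <- strain_efficiencies(tbl, focal, temperature)
  xr <- strain_efficiencies(tbl, reference, temperature)
  bg <- if ("genotype" %in% names(tbl)) {
    tbl$genotype[match(reference, tbl$strain_id)]
  } else NA_character_
  est <- new_effect_estimate(locus, bg, mean(xf) - mean(xr),
                             length(xf), length(xr))
  if (n_boot > 0) {
    est$boot <- bootstrap_effect_values(xf, xr, n_boot, seed = seed,
                                        ref_boot_means = ref_boot_means)
    est$ci <- boot_ci(est$boot, ci_level,
                      n_groups = c(length(xf), length(xr)))
    est$ci_level <- ci_level
  }
  est
}

#' Path-wise effect decomposition along a gene-stacking series
#'
#' For a series `S0 (wild-type), S1, ..., Sk` in which consecutive strains
#' differ by exactly one locus swap, the i-th effect is
#' `mean(Si) - mean(Si-1)`, attributed to the toggled locus (the effect of
#' the swap in the chimeric background it entered).
#'
#' @param tbl growth table with a `genotype` column
#' @param path ordered strain ids, wild-type first
#' @param temperature assay temperature
#' @param n_loci panel length (for genotype validation)
#' @inheritParams marginal_effect
#' @param loci locus tibble naming the panel bits
#' @return list of `effect_estimate`, one per step
#' @export
path_effects <- function(tbl, path, temperature, loci,
                         n_boot = 0, ci_level = 0.95, seed = NULL) {
  L <- nrow(loci)
  geno_of <- function(s) {
    g <- tbl$genotype[match(s, tbl$strain_id)]
    if (is.na(g)) stop("strain '", s, "' not in table")
    if (g == "recipient_wt") rep(0L, L)
    else if (g == "donor_wt") {
      stop("donor wild-type cannot appear in a swap path: it differs ",
           "genome-wide, not at one locus")
    } else genotype_bits(g, L)
  }
  bits <- lapply(path, geno_of)
  out <- vector("list", length(path) - 1L)
  for (i in seq_len(length(path) - 1L)) {
    d <- bits[[i + 1L]] - bits[[i]]
    if (sum(d == 1L) != 1L || any(d < 0L)) {
      stop("path validation: strains '", path[i], "' and '", path[i + 1L],
           "' do not differ by exactly one added locus")
    }
    step_seed <- if (is.null(seed)) NULL else seed + i
    out[[i]] <- marginal_effect(tbl, path[i + 1L], path[i], temperature,
                                locus = loci$name[which(d == 1L)],
                                n_boot = n_boot, ci_level = ci_level,
                                seed = step_seed)
  }
  out
}

#' Effect estimates as a tidy table
#' @param effects list of `effect_estimate`
#' @return tibble with columns locus, background, effect, ci_lo, ci_hi,
#'   n_focal, n_ref, n_boot
#' @export
effect_table <- function(effects) {
  if (!length(effects)) {
    return(tibble::tibble(locus = character(), background = character(),
                          effect = numeric(), ci_lo = numeric(),
                          ci_hi = numeric(), n_focal = integer(),
                          n_ref = integer(), n_boot = integer()))
  }
  dplyr::bind_rows(lapply(effects, function(e) {
    tibble::tibble(locus = e$locus, background = e$background,
                   effect = e$effect,
                   ci_lo = if (is.null(e$ci)) NA_real_ else e$ci[1],
                   ci_hi = if (is.null(e$ci)) NA_real_ else e$ci[2],
                   n_focal = e$n_focal, n_ref = e$n_ref,
                   n_boot = length(e$boot))
  }))
}

#' Fold change in mean growth efficiency between strains
#'
#' @inheritParams marginal_effect
#' @return `mean(focal) / mean(reference)`
#' @export
fold_change <- function(tbl, focal, reference, temperature) {
  mf <- mean(strain_efficiencies(tbl, focal, temperature))
  mr <- mean(strain_efficiencies(tbl, reference, temperature))
  if (mr <= 0) {
    stop("undefined ratio: reference mean efficiency is ", mr,
         " (must be > 0)")
  }
  mf / mr
}

#' Fraction of the interspecies trait divergence recapitulated
#'
#' `100 * (mean(transgenic) - mean(recipient_wt)) /
#'  (mean(donor_wt) - mean(recipient_wt))` on the linear efficiency scale.
#'
#' @param tbl growth table
#' @param transgenic,recipient_wt,donor_wt strain ids
#' @param temperature assay temperature
#' @return percent of divergence recapitulated
#' @export
recapitulation_fraction <- function(tbl, transgenic, recipient_wt,
                                    donor_wt, temperature) {
  mt <- mean(strain_efficiencies(tbl, transgenic, temperature))
  mr <- mean(strain_efficiencies(tbl, recipient_wt, temperature))
  md <- mean(strain_efficiencies(tbl, donor_wt, temperature))
  if (md == mr) stop("zero wild-type divergence: cannot form fraction")
  100 * (mt - mr) / (md - mr)
}

#' Wilcoxon rank-sum comparison of two strains
#'
#' Exact null distribution when the combined sample size is at most 25 and
#' there are no ties; otherwise the normal approximation with mid-rank tie
#' correction and continuity correction.
#'
#' @param tbl growth table, or `NULL` when `values_a`/`values_b` are given
#' @param a,b strain ids
#' @param temperature assay temperature
#' @param sidedness `"two_sided"`, `"greater"` (a shifted above b) or
#'   `"less"`
#' @param values_a,values_b direct value vectors, bypassing the table
#' @return list of class `comparison_result`: strain ids, rank-sum
#'   statistic, p-value, sidedness, sample sizes and a low-n flag (fewer
#'   than 3 replicates in a group)
#' @export
compare_strains <- function(tbl, a, b, temperature,
                            sidedness = c("two_sided", "greater", "less"),
                            values_a = NULL, values_b = NULL) {
  sidedness <- match.arg(sidedness)
  x <- if (is.null(values_a)) strain_efficiencies(tbl, a, temperature)
       else values_a
  y <- if (is.null(values_b)) strain_efficiencies(tbl, b, temperature)
       else values_b
  if (!length(x) || !length(y)) stop("empty group in comparison")
  alt <- switch(sidedness, two_sided = "two.sided", greater = "greater",
                less = "less")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 25 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = exact,
                       correct = TRUE))
  structure(list(strain_a = a, strain_b = b,
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 sidedness = sidedness, exact = exact,
                 n_a = length(x), n_b = length(y),
                 low_n = length(x) < 3 || length(y) < 3),
            class = "comparison_result")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals p-value family from one analysis run
#' @return q-values: monotone step-up adjusted values capped at 1
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' All pairwise strain comparisons with BH correction
#'
#' One invocation defines one multiple-testing family.
#'
#' @param tbl growth table
#' @param strains strain ids to compare (all unordered pairs)
#' @param temperature assay temperature
#' @param sidedness passed to [compare_strains()]
#' @return tibble with statistic, p and BH q per pair
#' @export
pairwise_comparisons <- function(tbl, strains, temperature,
                                 sidedness = "two_sided") {
  pairs <- utils::combn(strains, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    cr <- compare_strains(tbl, pairs[1, j], pairs[2, j], temperature,
                          sidedness)
    tibble::tibble(strain_a = cr$strain_a, strain_b = cr$strain_b,
                   statistic = cr$statistic, p_value = cr$p_value,
                   sidedness = cr$sidedness, n_a = cr$n_a, n_b = cr$n_b,
                   low_n = cr$low_n)
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- bh_adjust(out$p_value)
  out
}
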