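# Bootstrap additive-expectation null for epistasis: resampled per-locus
# effects, their iterate-wise sum as the expected joint phenotype under
# independent gene function, deviation (epsilon) of the observed joint
# effect, resampling significance, interaction-type classification, and the
# directional path-trend binomial test.

bootstrap_effect_values <- function(xf, xr, n_boot, seed = NULL,
                                    ref_boot_means = NULL) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (length(xf) < 2 || length(xr) < 2) {
    warning("degenerate bootstrap: a group has a single replicate")
  }
  with_seed(seed, {
    nf <- length(xf)
    fm <- .colMeans(xf[sample.int(nf, nf * n_boot, replace = TRUE)],
                    nf, n_boot)
    if (is.null(ref_boot_means)) {
      nr <- length(xr)
      ref_boot_means <- .colMeans(
        xr[sample.int(nr, nr * n_boot, replace = TRUE)], nr, n_boot)
    }
    fm - ref_boot_means
  })
}

#' Bootstrap distribution of a swap effect
#'
#' Each iterate independently resamples the focal strain's replicates and
#' the reference strain's replicates with replacement (at the original
#' sample sizes) and returns the difference of resampled means — one
#' bootstrapped estimate of the effect of the swap.
#'
#' @param tbl growth table
#' @param focal,reference strain ids
#' @param temperature assay temperature
#' @param n_boot iterations
#' @param seed RNG seed
#' @param ref_boot_means optional precomputed reference resampled means, to
#'   share one reference draw per iterate across several effects (used by
#'   [epistasis_analysis()])
#' @return numeric vector of length `n_boot`
#' @export
bootstrap_effect <- function(tbl, focal, reference, temperature, n_boot,
                             seed = NULL, ref_boot_means = NULL) {
  xf <- strain_efficiencies(tbl, focal, temperature)
  xr <- strain_efficiencies(tbl, reference, temperature)
  bootstrap_effect_values(xf, xr, n_boot, seed = seed,
                          ref_boot_means = ref_boot_means)
}

#' Additive expectation of a joint swap phenotype
#'
#' Sums single-locus effect means to the expected joint effect under
#' independent gene function, and sums the per-locus bootstrap distributions
#' iterate-wise: each iterate is one bootstrap's worth of the joint
#' phenotype estimate under the additive model.
#'
#' @param single_effects list of `effect_estimate`, one per locus, each
#'   carrying a bootstrap distribution of equal length
#' @return list of class `additive_expectation`: `expected` (point sum) and
#'   `boot` (iterate-wise sum)
#' @export
additive_expectation <- function(single_effects) {
  boots <- lapply(single_effects, `[[`, "boot")
  if (any(vapply(boots, is.null, logical(1)))) {
    stop("every single-locus effect needs a bootstrap distribution")
  }
  lens <- vapply(boots, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("mismatched bootstrap lengths: ", paste(lens, collapse = ", "))
  }
  structure(list(
    expected = sum(vapply(single_effects, `[[`, numeric(1), "effect")),
    boot = rowSums(do.call(cbind, boots))),
    class = "additive_expectation")
}

#' Test the observed joint effect against the additive expectation
#'
#' epsilon is the observed joint effect minus the additive point
#' expectation.  The p-value is the add-one-smoothed fraction of bootstrap
#' iterates in which the observed-minus-expected difference lies on or
#' beyond the null side: for alternative `"less"` (negative epistasis),
#' `p = (#\{d >= 0\} + 1) / (n_boot + 1)`; for `"two_sided"` the smaller
#' tail is doubled and capped at 1.
#'
#' @param observed `effect_estimate` of the multi-locus strain versus the
#'   recipient wild-type, with bootstrap
#' @param expected `additive_expectation`
#' @param alternative `"less"` or `"two_sided"`
#' @param alpha significance level for the magnitude label
#' @return list of class `epistasis_result`: `observed_joint`,
#'   `expected_additive`, `epsilon`, `boot_observed`, `boot_expected`,
#'   `p_value`, `label`
#' @export
epistasis_test <- function(observed, expected,
                           alternative = c("less", "two_sided"),
                           alpha = 0.05) {
  alternative <- match.arg(alternative)
  if (is.null(observed$boot)) stop("observed effect needs a bootstrap")
  n_boot <- length(observed$boot)
  if (n_boot != length(expected$boot)) {
    stop("observed and expected bootstrap lengths differ")
  }
  if (n_boot < 100) warning("n_boot < 100: p-value estimate is unstable")
  d <- observed$boot - expected$boot
  p_less <- (sum(d >= 0) + 1) / (n_boot + 1)
  p_greater <- (sum(d <= 0) + 1) / (n_boot + 1)
  p <- switch(alternative,
              less = p_less,
              two_sided = min(1, 2 * min(p_less, p_greater)))
  eps <- observed$effect - expected$expected
  label <- if (p <= alpha && eps < 0) "negative_magnitude"
           else if (p <= alpha && eps > 0) "positive_magnitude"
           else "none"
  structure(list(observed_joint = observed$effect,
                 expected_additive = expected$expected,
                 epsilon = eps,
                 boot_observed = observed$boot,
                 boot_expected = expected$boot,
                 p_value = p, alternative = alternative, label = label),
            class = "epistasis_result")
}

#' @export
print.epistasis_result <- function(x, ...) {
  cat(sprintf(
    "epistasis_result: observed=%.4g expected=%.4g epsilon=%.4g p=%.4g [%s]\n",
    x$observed_joint, x$expected_additive, x$epsilon, x$p_value, x$label))
  invisible(x)
}

#' Joint epistasis analysis of a multi-swap strain against its parts
#'
#' Runs the full additive-expectation construction with a statistically
#' coherent resampling scheme: ONE reference (wild-type) resample is drawn
#' per bootstrap iterate and shared across the observed joint effect and
#' every single-locus effect, so the bootstrap distribution of
#' observed-minus-expected reflects the true sampling variation of the
#' epsilon statistic (which reuses the same wild-type sample in all of its
#' terms).
#'
#' @param tbl growth table
#' @param joint strain id of the multi-locus swap strain
#' @param singles named character: single-swap strain id per locus (names
#'   are locus labels)
#' @param reference recipient wild-type strain id
#' @param temperature assay temperature
#' @param n_boot bootstrap iterations
#' @param alternative passed to [epistasis_test()]
#' @param alpha significance level
#' @param ci_level interval level for the per-effect intervals
#' @param seed RNG seed
#' @return list with `result` (`epistasis_result`), `observed`
#'   (`effect_estimate`), `single_effects` (list of `effect_estimate`)
#' @export
epistasis_analysis <- function(tbl, joint, singles, reference, temperature,
                               n_boot = 10000, alternative = "less",
                               alpha = 0.05, ci_level = 0.95, seed = NULL) {
  with_seed(seed, {
    xr <- strain_efficiencies(tbl, reference, temperature)
    nr <- length(xr)
    ref_means <- .colMeans(xr[sample.int(nr, nr * n_boot, replace = TRUE)],
                           nr, n_boot)
    observed <- marginal_effect(tbl, joint, reference, temperature,
                                locus = joint, n_boot = n_boot,
                                ci_level = ci_level,
                                ref_boot_means = ref_means)
    single_effects <- lapply(seq_along(singles), function(i) {
      marginal_effect(tbl, singles[[i]], reference, temperature,
                      locus = names(singles)[i], n_boot = n_boot,
                      ci_level = ci_level, ref_boot_means = ref_means)
    })
    names(single_effects) <- names(singles)
    expected <- additive_expectation(single_effects)
    list(result = epistasis_test(observed, expected, alternative, alpha),
         observed = observed,
         single_effects = single_effects,
         expected = expected)
  })
}

#' Classify a locus's interaction type from its effect alone vs in
#' combination
#'
#' Uses the bootstrap percentile intervals of the locus's effect when
#' swapped alone into the wild-type background versus its effect when
#' swapped into a multi-genic background: `sign` if both intervals exclude
#' 0 with opposite signs; `masking` if the lone effect excludes 0 but the
#' in-combination effect is indistinguishable from 0; negative/positive
#' `magnitude` if both exclude 0 with the same sign and the iterate-wise
#' difference of magnitudes excludes 0; otherwise `none`.
#'
#' @param alone `effect_estimate` with bootstrap (locus swapped alone)
#' @param in_combination `effect_estimate` with bootstrap (same locus
#'   entering a multi-genic background)
#' @param ci_level shared interval level
#' @return one of `"sign"`, `"masking"`, `"negative_magnitude"`,
#'   `"positive_magnitude"`, `"none"`
#' @export
classify_locus_interaction <- function(alone, in_combination,
                                       ci_level = 0.95) {
  if (is.null(alone$boot) || is.null(in_combination$boot)) {
    stop("both effect estimates need bootstrap distributions")
  }
  ci_a <- boot_ci(alone$boot, ci_level,
                  n_groups = c(alone$n_focal, alone$n_ref))
  ci_c <- boot_ci(in_combination$boot, ci_level,
                  n_groups = c(in_combination$n_focal, in_combination$n_ref))
  excl_a <- ci_a[1] > 0 || ci_a[2] < 0
  excl_c <- ci_c[1] > 0 || ci_c[2] < 0
  if (excl_a && excl_c && sign(alone$effect) != sign(in_combination$effect)) {
    return("sign")
  }
  if (excl_a && !excl_c) return("masking")
  if (excl_a && excl_c) {
    n <- min(length(alone$boot), length(in_combination$boot))
    d <- abs(in_combination$boot[seq_len(n)]) - abs(alone$boot[seq_len(n)])
    ci_d <- boot_ci(d, ci_level)
    if (ci_d[2] < 0) return("negative_magnitude")
    if (ci_d[1] > 0) return("positive_magnitude")
  }
  "none"
}

#' One-sided binomial test for a directional trend of path effects
#'
#' Counts beneficial steps along the stacking path and computes the exact
#' upper-tail binomial probability at null success probability 1/2:
#' `p = sum_{k = n_positive}^{n} C(n, k) 0.5^n`.
#'
#' @param path_fx list of `effect_estimate` (one per path step)
#' @param criterion `"point_positive"` (effect > 0) or
#'   `"significant_positive"` (bootstrap interval above 0)
#' @return list of class `trend_test_result`: `n_steps`, `n_positive`,
#'   `p_value`
#' @export
trend_binomial_test <- function(path_fx,
                                criterion = c("point_positive",
                                              "significant_positive")) {
  criterion <- match.arg(criterion)
  if (!length(path_fx)) stop("trend test needs at least one path step")
  pos <- vapply(path_fx, function(e) {
    switch(criterion,
           point_positive = e$effect > 0,
           significant_positive = {
             if (is.null(e$ci)) stop("criterion 'significant_positive' ",
                                     "needs bootstrap intervals")
             e$ci[1] > 0
           })
  }, logical(1))
  n <- length(pos)
  k <- sum(pos)
  p <- sum(choose(n, k:n)) / 2^n
  structure(list(n_steps = n, n_positive = k, p_value = p,
                 criterion = criterion),
            class = "trend_test_result")
}

#' @export
print.trend_test_result <- function(x, ...) {
  cat(sprintf("trend_test_result: %d/%d positive steps, binomial p = %.4g\n",
              x$n_positive, x$n_steps, x$p_value))
  invisible(x)
}
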