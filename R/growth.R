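# Phenotype readouts: growth efficiency (delta OD), bounded logistic fits to
# OD timecourses, and CFU/mL/OD viability from dilution-series spot counts.

#' Growth efficiency: final minus initial optical density
#'
#' The biomass-accumulation readout: the increase in OD600 over the fixed
#' incubation, sign preserved (a shrinking culture has negative efficiency).
#'
#' @param x growth table (gains an `efficiency` column) or numeric
#'   `od_initial`
#' @param od_final numeric, when `x` is `od_initial`
#' @return table with `efficiency` column, or numeric vector
#' @export
efficiency <- function(x, od_final = NULL) {
  if (is.data.frame(x)) {
    dplyr::mutate(x, efficiency = .data$od_final - .data$od_initial)
  } else {
    od_final - x
  }
}

logistic_od <- function(t, K, R, x0) K / (1 + exp(-R * (t - x0)))

#' Fit a bounded logistic growth curve to an OD timecourse
#'
#' Bounded nonlinear least squares of `od(t) = K / (1 + exp(-R (t - x0)))`
#' with every parameter constrained to `[-1, 10]` by default (carrying
#' capacity K in OD units, logistic rate R per day, sigmoidal midpoint x0 in
#' days).  Optimization is L-BFGS-B with analytic gradients from starts
#' K0 = max OD, R0 = 1/day, x0_0 = median timepoint; deterministic given the
#' start.
#'
#' Non-convergence is data, not failure: it is carried in the `converged`
#' flag (and such fits are excluded by [average_fit()] / [growth_rate()]).
#'
#' @param times days, strictly increasing, at least 4 points
#' @param ods optical densities, same length
#' @param bounds named list `lower`, `upper` (length-3 vectors for K, R, x0)
#' @param init optional length-3 start `c(K, R, x0)`
#' @return object of class `logistic_fit`: list with `K`, `R`, `x0`,
#'   `converged`, `residual_norm`, `boundary_active`
#' @export
fit_logistic <- function(times, ods,
                         bounds = list(lower = rep(-1, 3),
                                       upper = rep(10, 3)),
                         init = NULL) {
  if (length(times) != length(ods)) stop("times and ods lengths differ")
  if (length(times) < 4) {
    stop("insufficient data: logistic fit needs >= 4 timepoints, got ",
         length(times))
  }
  lo <- bounds$lower; up <- bounds$upper
  if (is.null(init)) {
    init <- c(max(ods), 1, stats::median(times))
  }
  init <- pmin(pmax(init, lo), up)
  obj <- function(p) {
    s <- 1 / (1 + exp(-p[2] * (times - p[3])))
    sum((p[1] * s - ods)^2)
  }
  grad <- function(p) {
    s <- 1 / (1 + exp(-p[2] * (times - p[3])))
    r <- p[1] * s - ods
    c(2 * sum(r * s),
      2 * sum(r * p[1] * s * (1 - s) * (times - p[3])),
      -2 * sum(r * p[1] * s * (1 - s) * p[2]))
  }
  ctrl <- list(factr = 1e1, pgtol = 1e-14, maxit = 1000)
  # projected Levenberg-Marquardt polish: L-BFGS-B stalls in the flat
  # valleys of small-residual problems; Gauss-Newton steps recover the
  # remaining digits
  polish <- function(p) {
    for (it in 1:50) {
      s <- 1 / (1 + exp(-p[2] * (times - p[3])))
      r <- p[1] * s - ods
      J <- cbind(s, p[1] * s * (1 - s) * (times - p[3]),
                 -p[1] * s * (1 - s) * p[2])
      g <- crossprod(J, r)
      H <- crossprod(J)
      step <- tryCatch(solve(H + 1e-12 * diag(3), g), error = function(e) NULL)
      if (is.null(step)) break
      cand <- pmin(pmax(p - drop(step), lo), up)
      if (obj(cand) <= obj(p)) {
        moved <- max(abs(cand - p)); p <- cand
        if (moved < 1e-12) break
      } else break
    }
    p
  }
  fit <- tryCatch({
    f1 <- stats::optim(init, obj, grad, method = "L-BFGS-B",
                       lower = lo, upper = up, control = ctrl)
    pp <- polish(f1$par)
    if (obj(pp) <= f1$value) f1$par <- pp
    f1$value <- obj(f1$par)
    f1
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(K = NA_real_, R = NA_real_, x0 = NA_real_,
                          converged = FALSE, residual_norm = NA_real_,
                          boundary_active = FALSE),
                     class = "logistic_fit"))
  }
  p <- unname(fit$par)
  tol <- 1e-8
  structure(list(K = p[1], R = p[2], x0 = p[3],
                 converged = fit$convergence == 0,
                 residual_norm = sqrt(fit$value),
                 boundary_active = any(p - lo < tol) || any(up - p < tol)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit: K=%.4g R=%.4g x0=%.4g | converged=%s rss^0.5=%.3g%s\n",
              x$K, x$R, x$x0, x$converged, x$residual_norm,
              if (isTRUE(x$boundary_active)) " [bound active]" else ""))
  invisible(x)
}

#' Average logistic fit across replicates
#'
#' Arithmetic mean of (K, R, x0) over converged replicate fits — the
#' "average fit" reported per strain; non-converged fits are excluded and
#' counted.
#'
#' @param fits list of `logistic_fit`
#' @return `logistic_fit` with averaged parameters and attribute
#'   `n_excluded`
#' @export
average_fit <- function(fits) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv)) stop("no converged fits to average")
  res <- structure(list(
    K = mean(vapply(conv, `[[`, numeric(1), "K")),
    R = mean(vapply(conv, `[[`, numeric(1), "R")),
    x0 = mean(vapply(conv, `[[`, numeric(1), "x0")),
    converged = TRUE,
    residual_norm = mean(vapply(conv, `[[`, numeric(1), "residual_norm")),
    boundary_active = any(vapply(conv, `[[`, logical(1), "boundary_active"))),
    class = "logistic_fit")
  attr(res, "n_excluded") <- length(fits) - length(conv)
  res
}

#' Per-replicate logistic growth rates for a strain
#'
#' Fits each replicate timecourse and returns the fitted rate R per
#' converged replicate, for downstream rank tests.  Non-converged replicates
#' are excluded and reported in the `excluded` attribute.
#'
#' @param tc timecourse table for one strain (columns `replicate`, `day`,
#'   `od`)
#' @param ... passed to [fit_logistic()]
#' @return named numeric vector of R values (one per converged replicate)
#' @export
growth_rate <- function(tc, ...) {
  if (!nrow(tc)) stop("empty timecourse table")
  reps <- split(tc, tc$replicate)
  fits <- lapply(reps, function(d) {
    d <- d[order(d$day), ]
    fit_logistic(d$day, d$od, ...)
  })
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv)) stop("all replicate fits failed to converge")
  out <- vapply(fits[conv], `[[`, numeric(1), "R")
  attr(out, "excluded") <- names(fits)[!conv]
  out
}

#' Quantify viability from a dilution-series spotting assay
#'
#' Selects the densest dilution at which every technical spot is countable
#' (not a lawn), averages the technical-replicate counts, and converts to
#' colony-forming units per mL of undiluted culture, then normalizes by the
#' end-point turbidity to account for dead cells that contribute to OD but
#' not viability.
#'
#' @param v viability table for one strain replicate (columns
#'   `dilution_exponent`, `tech_rep`, `colonies_or_LAWN`, `od_end`,
#'   `spot_volume_ml`)
#' @param lawn_threshold counts above this are treated as lawns too
#' @return list of class `viability_estimate`: `cfu_per_ml`,
#'   `cfu_per_ml_per_od`, `selected_dilution` (exponent), and flags
#'   `censored_above`, `below_detection`
#' @export
quantify_viability <- function(v, lawn_threshold = Inf) {
  stopifnot(length(unique(v$replicate)) <= 1)
  is_lawn <- v$colonies_or_LAWN == "LAWN" |
    suppressWarnings(as.numeric(v$colonies_or_LAWN)) > lawn_threshold
  exps <- sort(unique(v$dilution_exponent))
  usable <- vapply(exps, function(e) {
    all(!is_lawn[v$dilution_exponent == e])
  }, logical(1))
  base <- list(strain_id = unique(v$strain_id),
               replicate = unique(v$replicate))
  if (!any(usable)) {
    return(structure(c(base, list(
      cfu_per_ml = NA_real_, cfu_per_ml_per_od = NA_real_,
      selected_dilution = NA_integer_, censored_above = TRUE,
      below_detection = FALSE)), class = "viability_estimate"))
  }
  sel <- exps[usable][1L]  # densest countable (smallest exponent)
  sub <- v[v$dilution_exponent == sel, ]
  mean_count <- mean(as.numeric(sub$colonies_or_LAWN))
  spot_volume <- unique(sub$spot_volume_ml)
  cfu <- mean_count / spot_volume / 10^(-sel)
  structure(c(base, list(
    cfu_per_ml = cfu,
    cfu_per_ml_per_od = cfu / unique(sub$od_end),
    selected_dilution = sel,
    censored_above = FALSE,
    below_detection = mean_count == 0)), class = "viability_estimate")
}

#' Viability estimates for every strain replicate in a table
#'
#' @param tbl viability table (schema `"viability"`)
#' @inheritParams quantify_viability
#' @return tibble with one row per (strain, replicate)
#' @export
viability_table <- function(tbl, lawn_threshold = Inf) {
  keys <- unique(tbl[, c("strain_id", "replicate")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- tbl[tbl$strain_id == keys$strain_id[i] &
                 tbl$replicate == keys$replicate[i], ]
    est <- quantify_viability(sub, lawn_threshold)
    tibble::tibble(strain_id = est$strain_id, replicate = est$replicate,
                   cfu_per_ml = est$cfu_per_ml,
                   cfu_per_ml_per_od = est$cfu_per_ml_per_od,
                   selected_dilution = est$selected_dilution,
                   censored_above = est$censored_above,
                   below_detection = est$below_detection)
  })
  dplyr::bind_rows(rows)
}
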