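# Ground-truth-known synthetic panel generator.  Emulates the experimental
# design: 2-8 biological replicates per strain per day pooled over days,
# delta-OD growth efficiencies with strain-specific means and Gaussian
# replicate noise, logistic OD timecourses on the cold-incubation day grid,
# and Poisson colony counts across a 1:10 dilution series with lawn
# censoring.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Damping factor giving a target joint/additive effect fraction
#'
#' Under the magnitude-damping regime with equal per-locus effects, the joint
#' effect of stacking all `n_loci` loci is `(1 - f^n) / (n (1 - f))` of the
#' additive sum.  This solves for the per-addition factor `f` that yields a
#' requested fraction.
#'
#' @param fraction target joint effect as a fraction of the additive sum,
#'   in (0, 1]
#' @param n_loci number of stacked loci
#' @return damping factor in (0, 1]
#' @export
damping_factor_for_fraction <- function(fraction, n_loci) {
  stopifnot(fraction > 0, fraction <= 1, n_loci >= 2)
  if (fraction == 1) return(1)
  g <- function(f) (1 - f^n_loci) / (n_loci * (1 - f)) - fraction
  stats::uniroot(g, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

#' Construct a synthetic-panel configuration
#'
#' The defaults are the package's stated world for the eight-locus
#' thermotolerance panel at the hot assay temperature: recipient wild-type
#' efficiency 0.60 dOD, equal per-locus effects of 0.134 dOD (single-swap
#' benefit 1.22-fold), magnitude damping calibrated so the joint effect of
#' all eight loci is 60% of the additive sum (joint strain 2.07-fold over
#' the recipient), donor wild-type efficiency set so the joint strain
#' recapitulates 15% of the interspecies divergence, replicate noise 0.05
#' dOD, and 4 days x 2 replicates/day per strain.
#'
#' @param loci locus tibble
#' @param baseline_efficiency dOD of the all-recipient-allele genotype
#' @param per_locus_effects named numeric, dOD effect of each donor allele
#' @param interaction regime: a list with `type` one of `"additive"`,
#'   `"magnitude_damping"` (field `factor`), `"masking"` (fields `target`,
#'   `maskers`), `"sign"` (fields `target`, `context`)
#' @param donor_wt_efficiency dOD of the donor purebred (not the all-ones
#'   genotype: it differs genome-wide)
#' @param noise_sd replicate standard deviation of efficiency (dOD)
#' @param replicates_per_day biological replicates per day, in 2..8
#' @param n_days number of pooled experiment days
#' @param batch_shift optional per-day additive shift (length `n_days`,
#'   default all 0)
#' @param day_grid timecourse measurement days (first must be 0)
#' @param od_noise_sd timecourse OD noise sd
#' @param logistic_truth data frame `strain_id, K, R, x0` of true logistic
#'   parameters per strain
#' @param cfu_truth named numeric, true CFU/mL per strain
#' @param od_end_truth end-point turbidity used in viability normalization
#' @param viability_replicates biological replicates for viability assays
#' @param dilution_exponents 1:10 series exponents (factor `10^-e`)
#' @param tech_reps technical spots per dilution
#' @param spot_volume_ml spotted volume
#' @param lawn_threshold colony count above which a spot is an uncountable
#'   lawn
#' @param seed RNG seed; fixed seed implies identical output
#' @return object of class `synthetic_config`
#' @export
synthetic_config <- function(loci = panel_loci(),
                             baseline_efficiency = 0.60,
                             per_locus_effects = stats::setNames(
                               rep(0.134, nrow(loci)), loci$name),
                             interaction = list(type = "magnitude_damping",
                                                factor = NULL),
                             donor_wt_efficiency = NULL,
                             noise_sd = 0.05,
                             replicates_per_day = 2L,
                             n_days = 4L,
                             batch_shift = NULL,
                             day_grid = c(0, 4, 5, 7, 8, 9, 10, 11),
                             od_noise_sd = 0.03,
                             logistic_truth = NULL,
                             cfu_truth = NULL,
                             od_end_truth = 2.0,
                             viability_replicates = 3L,
                             dilution_exponents = 1:5,
                             tech_reps = 2L,
                             spot_volume_ml = 0.003,
                             lawn_threshold = 100,
                             seed = 1L) {
  loci <- tibble::as_tibble(loci)
  L <- nrow(loci)
  if (is.null(names(per_locus_effects))) {
    names(per_locus_effects) <- loci$name
  }
  stopifnot(setequal(names(per_locus_effects), loci$name))
  per_locus_effects <- per_locus_effects[loci$name]
  if (!is.list(interaction) || is.null(interaction$type) ||
      !interaction$type %in% c("additive", "magnitude_damping", "masking",
                               "sign")) {
    stop("unknown interaction regime: ",
         if (is.list(interaction)) interaction$type else interaction)
  }
  if (identical(interaction$type, "magnitude_damping") &&
      is.null(interaction$factor)) {
    interaction$factor <- damping_factor_for_fraction(0.6, L)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(replicates_per_day < 2) || any(replicates_per_day > 8)) {
    stop("replicates_per_day must lie in 2..8 (the emulated design)")
  }
  if (is.null(batch_shift)) batch_shift <- rep(0, n_days)
  if (length(batch_shift) != n_days) {
    stop("batch_shift must have length n_days")
  }
  joint_truth <- NULL  # filled below once regime known
  cfg <- structure(list(
    loci = loci, baseline_efficiency = baseline_efficiency,
    per_locus_effects = per_locus_effects, interaction = interaction,
    donor_wt_efficiency = donor_wt_efficiency, noise_sd = noise_sd,
    replicates_per_day = as.integer(replicates_per_day),
    n_days = as.integer(n_days), batch_shift = batch_shift,
    day_grid = day_grid, od_noise_sd = od_noise_sd,
    logistic_truth = logistic_truth, cfu_truth = cfu_truth,
    od_end_truth = od_end_truth,
    viability_replicates = as.integer(viability_replicates),
    dilution_exponents = as.integer(dilution_exponents),
    tech_reps = as.integer(tech_reps), spot_volume_ml = spot_volume_ml,
    lawn_threshold = lawn_threshold, seed = seed),
    class = "synthetic_config")
  if (is.null(cfg$donor_wt_efficiency)) {
    # donor purebred placed so the full swap recapitulates 15% of the
    # interspecies divergence in the stated world
    joint <- true_phenotype(cfg, bits_to_genotype(rep(1L, L)))
    cfg$donor_wt_efficiency <- baseline_efficiency +
      (joint - baseline_efficiency) / 0.15
  }
  if (is.null(cfg$logistic_truth)) {
    cfg$logistic_truth <- default_logistic_truth(L)
  }
  if (is.null(cfg$cfu_truth)) {
    cfg$cfu_truth <- c(recipient_wt = 2e5, donor_wt = 2e8,
                       stats::setNames(1.4e6, paste0("stack_", L)))
  }
  cfg
}

# cold-growth logistic truths: the recipient (cold-adapted) grows fastest,
# the donor purebred slowest, the full swap intermediate-low; phenomenological
# values on the OD/day scale of the cold incubation
default_logistic_truth <- function(L) {
  tibble::tibble(
    strain_id = c("recipient_wt", "donor_wt", paste0("stack_", L)),
    K = c(1.5, 1.0, 1.2),
    R = c(0.9, 0.45, 0.55),
    x0 = c(5, 8, 7)
  )
}

#' True (noise-free) growth efficiency of a genotype
#'
#' The generator's genotype-phenotype map.  Additive: baseline plus the sum
#' of active-locus effects.  Magnitude damping: the k-th active locus (in
#' panel locus order) contributes `effect * factor^(k-1)`.  Masking: the
#' target locus contributes nothing when any masker locus carries the donor
#' allele.  Sign: the target's effect is negated when any context locus
#' carries the donor allele.
#'
#' @param config `synthetic_config`
#' @param genotype bit-string or wild-type token
#' @return dOD efficiency
#' @export
true_phenotype <- function(config, genotype) {
  if (is_wt_token(genotype)) {
    return(if (genotype == "recipient_wt") config$baseline_efficiency
           else config$donor_wt_efficiency)
  }
  bits <- genotype_bits(genotype, nrow(config$loci))
  eff <- config$per_locus_effects
  active <- which(bits == 1L)
  reg <- config$interaction
  contrib <- switch(reg$type,
    additive = eff[active],
    magnitude_damping = eff[active] * reg$factor^(seq_along(active) - 1),
    masking = {
      e <- eff[active]
      nm <- config$loci$name[active]
      if (reg$target %in% nm &&
          any(config$loci$name[active] %in% reg$maskers)) {
        e[nm == reg$target] <- 0
      }
      e
    },
    sign = {
      e <- eff[active]
      nm <- config$loci$name[active]
      if (reg$target %in% nm &&
          any(config$loci$name[active] %in% reg$context)) {
        e[nm == reg$target] <- -e[nm == reg$target]
      }
      e
    },
    stop("unknown interaction regime: ", reg$type)
  )
  unname(config$baseline_efficiency + sum(contrib))
}

#' Generate a replicate growth-efficiency table
#'
#' For each strain, `n_days` batches of `replicates_per_day` replicates:
#' efficiency = true phenotype + day batch shift + Gaussian(0, noise_sd);
#' cultures start at OD 0.1 and the final OD is initial + efficiency after a
#' 24 h incubation.
#'
#' @param config `synthetic_config`
#' @param strains strain tibble (`strain_id`, `genotype`)
#' @param temperature assay temperature recorded in the table
#' @param seed RNG seed (default the config's)
#' @return growth table (see [read_measurements()] schema `"growth"`)
#' @export
generate_growth_panel <- function(config, strains, temperature = 39,
                                  seed = config$seed) {
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(strains)), function(i) {
      truth <- true_phenotype(config, strains$genotype[i])
      per_day <- lapply(seq_len(config$n_days), function(d) {
        n <- config$replicates_per_day
        eff <- truth + config$batch_shift[d] +
          stats::rnorm(n, 0, config$noise_sd)
        tibble::tibble(
          strain_id = strains$strain_id[i],
          genotype = strains$genotype[i],
          temperature_C = temperature,
          replicate = paste0("d", d, "_r", seq_len(n)),
          day = paste0("day_", d),
          od_initial = 0.1,
          od_final = 0.1 + eff,
          duration_h = 24)
      })
      dplyr::bind_rows(per_day)
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate logistic OD timecourses on the cold-incubation day grid
#'
#' @inheritParams generate_growth_panel
#' @return timecourse table; ODs are the logistic curve
#'   `K / (1 + exp(-R (t - x0)))` plus Gaussian noise, clamped at 0
#' @export
generate_timecourses <- function(config, strains, temperature = 4,
                                 seed = config$seed) {
  lt <- config$logistic_truth
  missing <- setdiff(strains$strain_id, lt$strain_id)
  if (length(missing)) {
    stop("logistic_truth missing for strain(s): ",
         paste(missing, collapse = ", "))
  }
  n_rep <- config$replicates_per_day * config$n_days
  t <- config$day_grid
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(strains)), function(i) {
      p <- lt[lt$strain_id == strains$strain_id[i], ]
      mu <- p$K / (1 + exp(-p$R * (t - p$x0)))
      per_rep <- lapply(seq_len(n_rep), function(r) {
        od <- mu + stats::rnorm(length(t), 0, config$od_noise_sd)
        tibble::tibble(strain_id = strains$strain_id[i],
                       temperature_C = temperature,
                       replicate = paste0("r", r),
                       day = t, od = pmax(od, 0))
      })
      dplyr::bind_rows(per_rep)
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a dilution-series viability table
#'
#' Per dilution `10^-e`, expected colonies are
#' `cfu_truth * spot_volume * 10^-e`; counts are Poisson draws per technical
#' spot, and counts above `lawn_threshold` are censored to the LAWN token.
#'
#' @inheritParams generate_growth_panel
#' @return viability table (schema `"viability"`)
#' @export
generate_viability <- function(config, strains, temperature = 39,
                               seed = config$seed) {
  missing <- setdiff(strains$strain_id, names(config$cfu_truth))
  if (length(missing)) {
    stop("cfu_truth missing for strain(s): ",
         paste(missing, collapse = ", "))
  }
  exps <- config$dilution_exponents
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(strains)), function(i) {
      cfu <- config$cfu_truth[[strains$strain_id[i]]]
      per_rep <- lapply(seq_len(config$viability_replicates), function(r) {
        grid <- expand.grid(dilution_exponent = exps,
                            tech_rep = seq_len(config$tech_reps))
        grid <- grid[order(grid$tech_rep, grid$dilution_exponent), ]
        lam <- cfu * config$spot_volume_ml * 10^(-grid$dilution_exponent)
        counts <- stats::rpois(nrow(grid), lam)
        tibble::tibble(
          strain_id = strains$strain_id[i],
          temperature_C = temperature,
          replicate = paste0("r", r),
          dilution_exponent = as.integer(grid$dilution_exponent),
          tech_rep = paste0("t", grid$tech_rep),
          colonies_or_LAWN = ifelse(counts > config$lawn_threshold, "LAWN",
                                    as.character(counts)),
          od_end = config$od_end_truth,
          spot_volume_ml = config$spot_volume_ml)
      })
      dplyr::bind_rows(per_rep)
    })
    dplyr::bind_rows(rows)
  })
}
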