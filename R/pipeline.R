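# End-to-end orchestration: simulate -> phenotypes -> effects -> epistasis
# -> report, with per-stage seeds derived from one run seed, a run manifest
# sufficient to reproduce outputs, and a plain-text log.

stage_seed <- function(seed, index) {
  # double-precision arithmetic avoids 32-bit overflow for large run seeds
  as.integer((as.numeric(seed) * 101 + index * 7919) %% 2147483647)
}

#' Run the panel analysis pipeline
#'
#' Executes the requested stages in dependency order.  All stochastic stages
#' consume seeds derived deterministically from the single run seed, so a
#' rerun with the same configuration is byte-identical and skipping a stage
#' never changes another stage's numbers.
#'
#' @param config `analysis_config`
#' @param out_dir output directory (created if absent)
#' @param syn synthetic-panel config used by the `simulate` stage; when no
#'   simulate stage runs, tidy input tables must already exist under
#'   `file.path(out_dir, "inputs")`
#' @param stages subset of `c("simulate", "growth", "viability", "effects",
#'   "epistasis", "report")`
#' @param seed run seed (default the config's `rng_seed`)
#' @return invisibly, a list with the run `manifest` and all stage results
#' @export
run_pipeline <- function(config, out_dir,
                         syn = synthetic_config(loci = config$loci),
                         stages = c("simulate", "growth", "viability",
                                    "effects", "epistasis", "report"),
                         seed = config$rng_seed) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("thermoswap %s | seed=%d | n_boot=%d alpha=%g ci_level=%g",
       as.character(utils::packageVersion("thermoswap")), as.integer(seed),
       config$n_boot, config$alpha, config$ci_level)
  logf("loci: %s | path: %s", paste(config$loci$name, collapse = ","),
       paste(config$path_order, collapse = ">"))
  logf("sidedness: %s",
       paste(names(config$sidedness), unlist(config$sidedness),
             sep = "=", collapse = " "))

  strains <- panel_strains(config$loci, config$path_order)
  refs <- config$reference_strains
  hot <- config$temperatures[1]
  results <- list()
  growth_path <- file.path(in_dir, "growth.csv")
  viab_path <- file.path(in_dir, "viability.csv")
  run_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", {
      g <- generate_growth_panel(syn, strains, hot,
                                 seed = stage_seed(seed, 1L))
      write_measurements(g, growth_path, "growth")
      v <- generate_viability(
        syn,
        strains[strains$strain_id %in% names(syn$cfu_truth), ],
        hot, seed = stage_seed(seed, 2L))
      write_measurements(v, viab_path, "viability")
      logf("simulate: %d growth rows, %d viability rows", nrow(g), nrow(v))
    })
  }

  growth_tbl <- NULL
  if (any(c("growth", "effects", "epistasis", "report") %in% stages)) {
    growth_tbl <- read_measurements(growth_path, "growth")
  }

  if ("growth" %in% stages) {
    run_stage("growth", {
      eff <- efficiency(growth_tbl)
      p <- file.path(out_dir, "growth_efficiency.csv")
      write_results(eff, p)
      results$growth <- eff
      logf("growth: efficiency for %d replicate cultures", nrow(eff))
    })
  }

  if ("viability" %in% stages) {
    run_stage("viability", {
      v <- read_measurements(viab_path, "viability")
      vt <- viability_table(v, lawn_threshold = syn$lawn_threshold)
      p <- file.path(out_dir, "viability_estimates.csv")
      write_results(vt, p)
      results$viability <- vt
      logf("viability: %d strain replicates quantified", nrow(vt))
    })
  }

  single_ids <- stats::setNames(paste0("single_", config$loci$name),
                                config$loci$name)
  if ("effects" %in% stages) {
    run_stage("effects", {
      s3 <- stage_seed(seed, 3L)
      singles_fx <- lapply(seq_along(single_ids), function(i) {
        marginal_effect(growth_tbl, single_ids[[i]], refs$recipient, hot,
                        locus = names(single_ids)[i],
                        n_boot = config$n_boot,
                        ci_level = config$ci_level, seed = s3 + i)
      })
      names(singles_fx) <- names(single_ids)
      path <- path_strain_ids(strains)
      path_fx <- path_effects(growth_tbl, path, hot, config$loci,
                              n_boot = config$n_boot,
                              ci_level = config$ci_level,
                              seed = stage_seed(seed, 4L))
      comp <- pairwise_comparisons(
        growth_tbl, strains$strain_id, hot,
        sidedness = config$sidedness$hot %||% "two_sided")
      fc <- fold_change(growth_tbl, refs$joint, refs$recipient, hot)
      recap <- recapitulation_fraction(growth_tbl, refs$joint,
                                       refs$recipient, refs$donor, hot)
      write_results(effect_table(singles_fx),
                    file.path(out_dir, "single_effects.csv"))
      write_results(effect_table(path_fx),
                    file.path(out_dir, "path_effects.csv"))
      write_results(comp, file.path(out_dir, "comparisons.csv"))
      results$effects <- list(singles = singles_fx, path = path_fx,
                               comparisons = comp, fold_change = fc,
                               recapitulation = recap)
      logf("effects: joint fold-change %.4g | recapitulation %.4g%%",
           fc, recap)
    })
  }

  if ("epistasis" %in% stages) {
    run_stage("epistasis", {
      ea <- epistasis_analysis(growth_tbl, refs$joint, single_ids,
                               refs$recipient, hot,
                               n_boot = config$n_boot,
                               alternative = "less", alpha = config$alpha,
                               ci_level = config$ci_level,
                               seed = stage_seed(seed, 5L))
      pe <- if (!is.null(results$effects)) results$effects$path
            else path_effects(growth_tbl, path_strain_ids(strains), hot,
                              config$loci, n_boot = config$n_boot,
                              ci_level = config$ci_level,
                              seed = stage_seed(seed, 4L))
      labels <- vapply(config$loci$name, function(lc) {
        step <- Filter(function(e) e$locus == lc, pe)[[1]]
        classify_locus_interaction(ea$single_effects[[lc]], step,
                                   ci_level = config$ci_level)
      }, character(1))
      trend <- trend_binomial_test(pe)
      res <- ea$result
      epi_tbl <- tibble::tibble(
        observed_joint = res$observed_joint,
        expected_additive = res$expected_additive,
        epsilon = res$epsilon, p_value = res$p_value,
        alternative = res$alternative, label = res$label,
        n_boot = length(res$boot_observed))
      write_results(epi_tbl, file.path(out_dir, "epistasis.csv"))
      write_results(tibble::tibble(locus = names(labels), label = labels),
                    file.path(out_dir, "locus_interactions.csv"))
      results$epistasis <- list(analysis = ea, labels = labels,
                                 trend = trend)
      logf("epistasis: epsilon %.4g p %.4g [%s]; trend %d/%d p %.4g",
           res$epsilon, res$p_value, res$label, trend$n_positive,
           trend$n_steps, trend$p_value)
    })
  }

  if ("report" %in% stages) {
    run_stage("report", {
      txt <- report_summary(results, temperature = hot)
      writeLines(txt, file.path(out_dir, "summary.txt"))
    })
  }

  inputs_present <- Filter(file.exists, c(growth_path, viab_path))
  manifest <- list(
    tool = "thermoswap",
    version = as.character(utils::packageVersion("thermoswap")),
    seed = as.integer(seed),
    stages = stages,
    config = list(loci = config$loci$name, path_order = config$path_order,
                  temperatures = config$temperatures,
                  n_boot = config$n_boot, alpha = config$alpha,
                  ci_level = config$ci_level,
                  sidedness = config$sidedness),
    input_checksums = as.list(tools::md5sum(inputs_present)),
    outputs = list.files(out_dir, recursive = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(manifest = manifest, out_dir = out_dir)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Human-readable summary of pipeline results
#'
#' One document listing the headline metrics: fold-change, recapitulation
#' fraction, per-locus effects alone vs in combination, epistasis epsilon
#' and labels, and the path-trend binomial p.  Sections for stages that did
#' not run are empty.
#'
#' @param results stage-results list as assembled by [run_pipeline()]
#' @param temperature assay temperature to report
#' @return character vector of report lines
#' @export
report_summary <- function(results, temperature = NA) {
  out <- c("== panel analysis summary ==",
           sprintf("assay temperature: %s C", temperature))
  if (!is.null(results$effects)) {
    fx <- results$effects
    out <- c(out, "",
             sprintf("joint fold-change vs recipient wild-type: %.15g",
                     fx$fold_change),
             sprintf("recapitulation of interspecies divergence: %.15g%%",
                     fx$recapitulation),
             "", "per-locus effects (alone | entering the path):")
    for (lc in names(fx$singles)) {
      step <- Filter(function(e) e$locus == lc, fx$path)
      out <- c(out, sprintf("  %-6s %.15g | %s", lc,
                            fx$singles[[lc]]$effect,
                            if (length(step))
                              sprintf("%.15g", step[[1]]$effect)
                            else "not on path"))
    }
  }
  out <- c(out, "", "epistasis:")
  if (!is.null(results$epistasis)) {
    res <- results$epistasis$analysis$result
    tr <- results$epistasis$trend
    out <- c(out,
             sprintf("  observed joint effect: %.15g", res$observed_joint),
             sprintf("  additive expectation:  %.15g", res$expected_additive),
             sprintf("  epsilon: %.15g (p = %.15g, %s)", res$epsilon,
                     res$p_value, res$label),
             sprintf("  locus interaction labels: %s",
                     paste(names(results$epistasis$labels),
                           results$epistasis$labels, sep = "=",
                           collapse = " ")),
             sprintf("  path trend: %d/%d beneficial steps, binomial p = %.15g",
                     tr$n_positive, tr$n_steps, tr$p_value))
  } else {
    out <- c(out, "  (stage not run)")
  }
  if (!is.null(results$viability)) {
    vt <- results$viability
    out <- c(out, "", "viability (CFU/mL/OD, mean over replicates):")
    for (s in unique(vt$strain_id)) {
      m <- mean(vt$cfu_per_ml_per_od[vt$strain_id == s], na.rm = TRUE)
      out <- c(out, sprintf("  %-14s %.6g", s, m))
    }
  }
  out
}
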