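# Tidy-table I/O.  All tables are comma-delimited with header, UTF-8,
# "." decimal; censored lawn spots are the literal token LAWN.  Floats are
# serialized at full precision (17 significant digits) so write/read round
# trips are bit-exact.

.schemas <- list(
  growth = list(
    cols = c("strain_id", "genotype", "temperature_C", "replicate", "day",
             "od_initial", "od_final", "duration_h"),
    classes = c("character", "character", "numeric", "character",
                "character", "numeric", "numeric", "numeric"),
    validate = "validate_growth"
  ),
  timecourse = list(
    cols = c("strain_id", "temperature_C", "replicate", "day", "od"),
    classes = c("character", "numeric", "character", "numeric", "numeric"),
    validate = "validate_timecourse"
  ),
  viability = list(
    cols = c("strain_id", "temperature_C", "replicate", "dilution_exponent",
             "tech_rep", "colonies_or_LAWN", "od_end", "spot_volume_ml"),
    classes = c("character", "numeric", "character", "integer", "character",
                "character", "numeric", "numeric"),
    validate = "validate_viability"
  )
)

fmt_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

#' Read a tidy measurement table
#'
#' @param path file location of a comma-delimited table with header
#' @param schema one of `"growth"`, `"timecourse"`, `"viability"`
#' @return tibble of validated records, row order preserved; attribute
#'   `parse_report` records rows skipped as blank
#' @export
read_measurements <- function(path, schema = c("growth", "timecourse",
                                               "viability")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- .schemas[[schema]]
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  missing <- setdiff(sc$cols, header)
  if (length(missing)) {
    stop("schema '", schema, "': missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, blank.lines.skip = TRUE,
                         fileEncoding = "UTF-8")
  blank <- apply(raw == "" | is.na(raw), 1L, all)
  tbl <- raw[!blank, sc$cols, drop = FALSE]
  for (j in seq_along(sc$cols)) {
    cl <- sc$classes[j]
    if (cl == "numeric") tbl[[j]] <- as.numeric(tbl[[j]])
    if (cl == "integer") tbl[[j]] <- as.integer(tbl[[j]])
  }
  tbl <- tibble::as_tibble(tbl)
  do.call(sc$validate, list(tbl))
  attr(tbl, "parse_report") <- list(n_read = nrow(raw),
                                    skipped_blank = which(blank))
  tbl
}

#' Write a tidy measurement table
#'
#' @param tbl table of records matching a schema
#' @param path output file
#' @inheritParams read_measurements
#' @export
write_measurements <- function(tbl, path, schema = c("growth", "timecourse",
                                                     "viability")) {
  schema <- match.arg(schema)
  sc <- .schemas[[schema]]
  missing <- setdiff(sc$cols, names(tbl))
  if (length(missing)) {
    stop("cannot write schema '", schema, "': missing column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- tbl[, sc$cols, drop = FALSE]
  out[] <- lapply(out, fmt_full)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a result table with a structured summary sidecar
#'
#' Writes any stage output as a full-precision delimited table, plus a JSON
#' summary document (`<path>.summary.json`) listing the columns, row count
#' and numeric column ranges, so downstream readers can sanity-check without
#' parsing the table.
#'
#' @param results data frame of results (an empty frame yields a header-only
#'   table)
#' @param path output CSV path
#' @return invisibly, the path
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results)
  out <- results
  out[] <- lapply(out, fmt_full)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to ", path, ": ",
                        conditionMessage(ok))
  num <- vapply(results, is.numeric, logical(1))
  summ <- list(
    path = basename(path),
    n_rows = nrow(results),
    columns = names(results),
    numeric_ranges = lapply(results[num],
                            function(x) if (length(x)) range(x) else NULL)
  )
  jsonlite::write_json(summ, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back a result table written by [write_results()]
#' @param path CSV path
#' @return tibble with numeric columns restored
#' @export
read_results <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                    fileEncoding = "UTF-8"))
}

# ---- analysis configuration ------------------------------------------------

#' Construct an analysis configuration
#'
#' Central run parameters shared by all stages.  The locus order here is the
#' single source of truth for genotype bit alignment.
#'
#' @param loci locus tibble (see [locus_table()]); default the eight-gene
#'   panel
#' @param path_order stacking order of loci; must use distinct loci from
#'   `loci` (a prefix of a permutation)
#' @param reference_strains named list with `recipient`, `donor`, `joint`
#'   strain ids
#' @param temperatures numeric vector of assay temperatures (degrees C)
#' @param n_boot bootstrap iterations (default 10000)
#' @param alpha significance level
#' @param ci_level bootstrap interval level
#' @param rng_seed integer seed; the documented default is 1
#' @param sidedness named list mapping comparison families to
#'   `"greater"`/`"less"`/`"two_sided"` (heat assays are one-tailed,
#'   the control temperature two-tailed)
#' @return object of class `analysis_config`
#' @export
analysis_config <- function(loci = panel_loci(),
                            path_order = loci$name,
                            reference_strains = list(
                              recipient = "recipient_wt",
                              donor = "donor_wt",
                              joint = paste0("stack_", nrow(loci))),
                            temperatures = c(39, 28),
                            n_boot = 10000L,
                            alpha = 0.05,
                            ci_level = 0.95,
                            rng_seed = 1L,
                            sidedness = list(hot = "greater",
                                             control = "two_sided",
                                             cold = "less")) {
  loci <- tibble::as_tibble(loci)
  if (!all(c("name", "functional_class") %in% names(loci))) {
    stop("loci must have columns name, functional_class")
  }
  unknown <- setdiff(path_order, loci$name)
  if (length(unknown)) {
    stop("path order references unknown locus: ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(path_order)) stop("path order has duplicate loci")
  if (!is.numeric(n_boot) || n_boot < 1) stop("n_boot must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!(ci_level > 0 && ci_level < 1)) stop("ci_level must be in (0, 1)")
  structure(list(loci = loci, path_order = path_order,
                 reference_strains = reference_strains,
                 temperatures = temperatures,
                 n_boot = as.integer(n_boot), alpha = alpha,
                 ci_level = ci_level, rng_seed = as.integer(rng_seed),
                 sidedness = sidedness),
            class = "analysis_config")
}

#' Read an analysis configuration from a JSON file
#'
#' Missing fields take the documented defaults of [analysis_config()]
#' (n_boot 10000, alpha 0.05, ci_level 0.95, rng_seed 1).
#'
#' @param path JSON config file
#' @return `analysis_config`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$loci)) {
    if (is.character(raw$loci)) {
      args$loci <- locus_table(raw$loci)
    } else {
      args$loci <- locus_table(raw$loci$name, raw$loci$functional_class)
    }
  }
  for (f in c("path_order", "temperatures", "n_boot", "alpha", "ci_level",
              "rng_seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$reference_strains)) {
    args$reference_strains <- as.list(raw$reference_strains)
  }
  if (!is.null(raw$sidedness)) args$sidedness <- as.list(raw$sidedness)
  do.call(analysis_config, args)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:", nrow(x$loci), "loci |",
      "path:", paste(x$path_order, collapse = ">"), "\n")
  cat("  temperatures:", paste(x$temperatures, collapse = ", "),
      "C | n_boot:", x$n_boot, "| alpha:", x$alpha,
      "| ci_level:", x$ci_level, "| seed:", x$rng_seed, "\n")
  invisible(x)
}
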