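#' thermoswap: combinatorial allele-swap panel analysis
#'
#' Quantitative dissection of a polygenic temperature-tolerance trait from a
#' combinatorial allele-replacement strain panel: growth/viability
#' phenotyping, per-locus effect estimation across genetic backgrounds,
#' bootstrap additive-expectation epistasis testing and classification, and
#' temperature-tradeoff metrics, together with a ground-truth-known synthetic
#' panel generator.
#'
#' @keywords internal
#' @aliases thermoswap-package
#' @importFrom rlang .data
#' @importFrom tibble tibble
#' @importFrom dplyr bind_rows
"_PACKAGE"

# Reserved genotype tokens for purebred wild-types.  The donor wild-type is
# NOT the all-ones genotype: it differs from the recipient genome-wide, not
# just at the swapped loci, so it gets its own token rather than a bit-string.
.wt_tokens <- c("recipient_wt", "donor_wt")

#' Default functional-class vocabulary for panel loci
#' @return character vector of allowed functional classes
#' @export
locus_classes <- function() {
  c("mitotic", "chromatin-binding", "ribosome-biogenesis",
    "transcription-translation", "other")
}

#' Build a validated locus table
#'
#' A panel is defined over an ordered list of loci; genotype bit-strings are
#' aligned to this order.
#'
#' @param name character vector of unique short gene labels
#' @param functional_class character vector (recycled) drawn from `vocab`
#' @param vocab allowed functional classes
#' @return tibble with columns `name`, `functional_class`
#' @export
locus_table <- function(name, functional_class = "other",
                        vocab = locus_classes()) {
  if (anyDuplicated(name)) {
    stop("locus names must be unique within a panel: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  functional_class <- rep_len(functional_class, length(name))
  bad <- setdiff(unique(functional_class), vocab)
  if (length(bad)) {
    stop("functional_class not in vocabulary: ", paste(bad, collapse = ", "))
  }
  tibble::tibble(name = as.character(name),
                 functional_class = as.character(functional_class))
}

#' The eight-locus thermotolerance panel
#'
#' The default panel: eight unlinked genes whose donor-species alleles were
#' swapped, singly and in combination, into the recipient species.  Most are
#' annotated in chromosome segregation / mitosis.
#'
#' @return locus tibble of the eight genes in stacking-path order
#' @export
panel_loci <- function() {
  locus_table(
    name = c("DYN1", "MYO1", "SCC2", "APC1", "CEP3", "ESP1", "AFG2", "TAF2"),
    functional_class = c("mitotic", "mitotic", "mitotic", "mitotic",
                         "mitotic", "mitotic", "ribosome-biogenesis",
                         "chromatin-binding")
  )
}

#' Parse and validate a genotype bit-string
#'
#' @param genotype a bit-string such as `"10100000"`, or one of the reserved
#'   wild-type tokens `"recipient_wt"` / `"donor_wt"`
#' @param n_loci expected panel length
#' @return integer vector of 0/1 of length `n_loci`, or the token unchanged
#'   for wild-types
#' @export
genotype_bits <- function(genotype, n_loci) {
  if (length(genotype) != 1L) stop("genotype must be a single string")
  if (genotype %in% .wt_tokens) return(genotype)
  ch <- strsplit(genotype, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% c("0", "1"))) {
    stop("genotype must contain only 0/1 bits or be a wild-type token, got: ",
         genotype)
  }
  if (length(ch) != n_loci) {
    stop("genotype length ", length(ch), " does not match panel locus count ",
         n_loci)
  }
  as.integer(ch)
}

#' @rdname genotype_bits
#' @param bits integer 0/1 vector
#' @export
bits_to_genotype <- function(bits) paste(as.integer(bits), collapse = "")

is_wt_token <- function(genotype) genotype %in% .wt_tokens

#' Strain records for the standard swap panel
#'
#' Builds the strain table the experiment used: the two purebred wild-types,
#' each single-locus swap strain, and the cumulative gene-stacking series
#' culminating in the full swap (the all-donor-allele strain at the panel
#' loci).
#'
#' @param loci locus tibble (see [locus_table()])
#' @param path_order character vector: order in which loci are stacked;
#'   must be a permutation of `loci$name`
#' @return tibble with columns `strain_id`, `genotype`, `description`
#' @export
panel_strains <- function(loci = panel_loci(), path_order = loci$name) {
  if (!setequal(path_order, loci$name) ||
      length(path_order) != nrow(loci)) {
    stop("path_order must be a permutation of the panel loci")
  }
  L <- nrow(loci)
  idx <- match(path_order, loci$name)
  singles <- vapply(seq_len(L), function(i) {
    b <- integer(L); b[loci$name == loci$name[i]] <- 1L
    bits_to_genotype(b)
  }, character(1))
  stacks <- vapply(seq_len(L), function(k) {
    b <- integer(L); b[idx[seq_len(k)]] <- 1L
    bits_to_genotype(b)
  }, character(1))
  tibble::tibble(
    strain_id = c("recipient_wt", "donor_wt",
                  paste0("single_", loci$name),
                  paste0("stack_", seq_len(L))),
    genotype = c("recipient_wt", "donor_wt", singles, stacks),
    description = c("recipient-species purebred wild-type",
                    "donor-species purebred wild-type",
                    paste0("single swap of ", loci$name),
                    paste0("cumulative swap of first ", seq_len(L),
                           " loci in path order"))
  )
}

#' Strain ids of the cumulative stacking path, wild-type first
#' @param strains strain tibble from [panel_strains()]
#' @return character vector `recipient_wt, stack_1, ..., stack_L`
#' @export
path_strain_ids <- function(strains) {
  c("recipient_wt", sort_stack_ids(grep("^stack_", strains$strain_id,
                                        value = TRUE)))
}

sort_stack_ids <- function(ids) {
  ids[order(as.integer(sub("^stack_", "", ids)))]
}

# ---- record validators -----------------------------------------------------

stop_row <- function(i, msg) {
  stop(sprintf("row %d: %s", i, msg), call. = FALSE)
}

validate_growth <- function(tbl) {
  for (i in seq_len(nrow(tbl))) {
    if (is.na(tbl$od_initial[i]) || tbl$od_initial[i] < 0) {
      stop_row(i, sprintf("od_initial must be >= 0 (got %s)",
                          tbl$od_initial[i]))
    }
    if (is.na(tbl$duration_h[i]) || tbl$duration_h[i] <= 0) {
      stop_row(i, sprintf("duration_h must be > 0 (got %s)",
                          tbl$duration_h[i]))
    }
  }
  invisible(tbl)
}

validate_timecourse <- function(tbl) {
  key <- paste(tbl$strain_id, tbl$temperature_C, tbl$replicate)
  for (k in unique(key)) {
    sub <- tbl[key == k, ]
    if (is.unsorted(sub$day, strictly = TRUE)) {
      stop("timecourse for ", k, ": days must be strictly increasing",
           call. = FALSE)
    }
    if (sub$day[1L] != 0) {
      stop("timecourse for ", k, ": first timepoint must be day 0",
           call. = FALSE)
    }
  }
  invisible(tbl)
}

validate_viability <- function(tbl) {
  for (i in seq_len(nrow(tbl))) {
    if (is.na(tbl$od_end[i]) || tbl$od_end[i] <= 0) {
      stop_row(i, sprintf("od_end must be > 0 (got %s)", tbl$od_end[i]))
    }
    v <- tbl$colonies_or_LAWN[i]
    if (v != "LAWN") {
      n <- suppressWarnings(as.numeric(v))
      if (is.na(n) || n < 0 || n != round(n)) {
        stop_row(i, sprintf(
          "colonies_or_LAWN must be a non-negative integer or LAWN (got %s)",
          v))
      }
    }
  }
  # dilution factors strictly decreasing <=> exponents strictly increasing
  key <- paste(tbl$strain_id, tbl$temperature_C, tbl$replicate, tbl$tech_rep)
  for (k in unique(key)) {
    sub <- tbl[key == k, ]
    if (is.unsorted(sub$dilution_exponent, strictly = TRUE)) {
      stop("viability series for ", k,
           ": dilution exponents must be strictly increasing (factors ",
           "strictly decreasing)", call. = FALSE)
    }
  }
  invisible(tbl)
}
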