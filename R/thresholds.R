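#' Threshold schemes for differential-expression selection
#'
#' A scheme bundles the p-value gate, the per-layer fold-change magnitude
#' cutoffs, the stratification grid used for regulation-frequency tables, and
#' whether cutoff comparisons are inclusive. Two named presets exist:
#'
#' * `"case_study"` — the cutoffs of the meta-analysis itself:
#'   miRNA/gene |FC| >= 2.0, protein >= 1.5, metabolite >= 1.3.
#' * `"curation"` — the database-curation variant: miRNA/gene |FC| >= 2.0,
#'   protein and metabolite >= 1.3.
#'
#' @param preset `"case_study"` or `"curation"`, or `NULL` when supplying
#'   `de_fc_cutoff` directly.
#' @param p_cutoff p-value gate; records are retained when `p < p_cutoff`.
#' @param de_fc_cutoff named numeric vector mapping layers (MIR, GENE, PRO,
#'   MET) to fold-change magnitude cutoffs, each > 1. Overrides the preset.
#' @param strata ordered fold-change magnitudes used for frequency
#'   stratification; strictly increasing, each > 1.
#' @param inclusive logical; if `TRUE` (default) cutoffs compare with `>=`.
#' @return An object of class `threshold_scheme`.
#' @examples
#' threshold_scheme("case_study")
#' threshold_scheme("curation")$de_fc_cutoff
#' @export
threshold_scheme <- function(preset = c("case_study", "curation"),
                             p_cutoff = 0.05,
                             de_fc_cutoff = NULL,
                             strata = c(1.3, 1.5, 2.0),
                             inclusive = TRUE) {
  presets <- list(
    case_study = c(MIR = 2.0, GENE = 2.0, PRO = 1.5, MET = 1.3),
    curation   = c(MIR = 2.0, GENE = 2.0, PRO = 1.3, MET = 1.3)
  )
  if (is.null(de_fc_cutoff)) {
    preset <- match.arg(preset)
    de_fc_cutoff <- presets[[preset]]
    name <- preset
  } else {
    name <- "custom"
    check_layers(names(de_fc_cutoff), "de_fc_cutoff name")
  }
  if (any(de_fc_cutoff <= 1)) abort("Fold-change cutoffs must each be > 1.")
  if (any(strata <= 1) || is.unsorted(strata, strictly = TRUE)) {
    abort("`strata` must be strictly increasing and each > 1.")
  }
  if (!is.numeric(p_cutoff) || p_cutoff <= 0 || p_cutoff > 1) {
    abort("`p_cutoff` must lie in (0, 1].")
  }
  structure(
    list(name = name, p_cutoff = p_cutoff, de_fc_cutoff = de_fc_cutoff,
         strata = strata, inclusive = isTRUE(inclusive)),
    class = "threshold_scheme"
  )
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat("<threshold_scheme:", x$name, ">\n")
  cat("  p <", x$p_cutoff, "\n")
  cmp <- if (x$inclusive) ">=" else ">"
  cat("  |FC|", cmp,
      paste(sprintf("%s: %.1f", names(x$de_fc_cutoff), x$de_fc_cutoff),
            collapse = ", "), "\n")
  cat("  strata:", paste(x$strata, collapse = ", "), "\n")
  invisible(x)
}
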