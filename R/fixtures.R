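#' Packaged CAD study table
#'
#' Transcription of the coronary-artery-disease study descriptor table that
#' the meta-analysis draws on: 21 human blood studies (2 miRNA, 9 protein,
#' 10 metabolite). Cells merged in the printed original (omics type,
#' compartment, control group, detection method) are filled forward, and the
#' study range `Exp27350024a1-a5` is expanded to five rows.
#'
#' @return A tibble of study metadata (same columns as
#'   [read_study_metadata()]).
#' @examples
#' dplyr::count(cad_studies(), layer)
#' @export
cad_studies <- function() {
  read_study_metadata(
    system.file("extdata", "cad_studies.tsv", package = "omicsvote",
                mustWork = TRUE)
  )
}

#' Packaged most-reported-molecules table
#'
#' Transcription of the most-reported CAD molecules table: 76 molecules
#' (18 microRNAs, 16 proteins, 42 metabolites) reported in at least two
#' studies, with the frequency (%) of down-/up-regulation and
#' non-regulation at each fold-change stratum (1.3, 1.5, 2.0), the report
#' count, and the functional tag. Integer-valued cells are printed as
#' integers in the source (display truncation); they are kept verbatim.
#'
#' @param long logical; if `TRUE`, return the tidy long layout of
#'   [regulation_frequency_table()] (one row per molecule x stratum).
#' @return A tibble.
#' @examples
#' dplyr::count(cad_reported_molecules(), layer)
#' @export
cad_reported_molecules <- function(long = FALSE) {
  wide <- readr::read_tsv(
    system.file("extdata", "cad_reported_molecules.tsv",
                package = "omicsvote", mustWork = TRUE),
    show_col_types = FALSE
  )
  if (!long) return(wide)
  wide |>
    tidyr::pivot_longer(
      cols = dplyr::matches("^(down|up|nr)\\d+$"),
      names_to = c("what", "stratum"),
      names_pattern = "^(down|up|nr)(\\d+)$",
      values_to = "pct"
    ) |>
    dplyr::mutate(stratum = as.numeric(.data$stratum) / 10) |>
    tidyr::pivot_wider(names_from = "what", values_from = "pct",
                       names_glue = "{what}_pct") |>
    dplyr::rename(molecule_id = "molecule") |>
    dplyr::relocate("molecule_id", "layer", "tag", "reported", "stratum",
                    "down_pct", "up_pct", "nr_pct")
}

#' Write the packaged fixture tables to files
#'
#' Copies the packaged transcriptions byte-identically to `path`; rewriting
#' produces an identical file.
#'
#' @param path destination file path.
#' @return Invisibly, `path`.
#' @export
write_table1_fixture <- function(path) {
  src <- system.file("extdata", "cad_studies.tsv", package = "omicsvote",
                     mustWork = TRUE)
  file.copy(src, path, overwrite = TRUE)
  invisible(path)
}

#' @rdname write_table1_fixture
#' @export
write_table2_fixture <- function(path) {
  src <- system.file("extdata", "cad_reported_molecules.tsv",
                     package = "omicsvote", mustWork = TRUE)
  file.copy(src, path, overwrite = TRUE)
  invisible(path)
}
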