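#' Read a per-study differential-expression table
#'
#' Expression tables are TSV files with header columns `study_id`, `molecule`,
#' `layer`, `fc`, `p_value`, `compartment`, `species`. The fold-change dialect
#' (`"signed"` or `"ratio"`) is declared per file and canonicalized on read.
#'
#' @param path path to the TSV file.
#' @param fc_dialect fold-change dialect of the `fc` column.
#' @return A tibble of canonical expression records (columns `study_id`,
#'   `molecule_id`, `layer`, `fc`, `magnitude`, `direction`, `p_value`,
#'   `compartment`, `species`).
#' @export
read_expression_table <- function(path, fc_dialect = c("signed", "ratio")) {
  fc_dialect <- match.arg(fc_dialect)
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("study_id", "molecule", "layer", "fc", "p_value")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw <- dplyr::rename(raw, molecule_id = "molecule")
  for (extra in c("compartment", "species")) {
    if (!extra %in% names(raw)) raw[[extra]] <- NA_character_
  }
  validate_records(canonicalize_records(raw, fc_dialect))
}

#' Validate canonical expression records
#'
#' Checks the record invariants: recognised omics layers, p-values in (0, 1],
#' and magnitude/direction consistency with the signed fold-change.
#'
#' @param records tibble of canonical expression records.
#' @return `records`, invisibly coerced to a tibble, if valid; otherwise an
#'   error.
#' @export
validate_records <- function(records) {
  records <- tibble::as_tibble(records)
  check_layers(records$layer)
  if (any(records$p_value <= 0 | records$p_value > 1)) {
    abort("p-values must lie in (0, 1]; zero or negative values are invalid.")
  }
  if (any(records$magnitude < 1)) {
    abort("Canonical fold-change magnitudes must be >= 1.")
  }
  if (!all(records$direction %in% c("up", "down", "none"))) {
    abort("`direction` must be 'up', 'down' or 'none'.")
  }
  records
}

#' Read study metadata
#'
#' Study metadata tables are TSV files with columns `study_id`, `layer`,
#' `compartment`, `n_total`, `case_label`, `control_label`,
#' `detection_method`.
#'
#' @param path path to the TSV file.
#' @return A tibble of study metadata; errors if `study_id` is not unique.
#' @export
read_study_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("study_id", "layer", "compartment", "n_total",
              "case_label", "control_label", "detection_method")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$study_id)) {
    abort("`study_id` must be unique within a metadata table.")
  }
  check_layers(meta$layer)
  if (any(meta$n_total < 1)) abort("`n_total` must be >= 1.")
  meta
}

#' Read a molecule cluster/synonym table
#'
#' One synonym per line, columns `cluster_id`, `synonym`, `tag` and optional
#' `external_db`, `external_id`. Synonym matching everywhere is
#' case-insensitive after whitespace normalisation, so a synonym may not be
#' claimed (even in a different case) by two clusters.
#'
#' @param path path to the TSV file.
#' @return A tibble with a normalised `synonym_key` column added.
#' @export
read_cluster_table <- function(path) {
  clusters <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("cluster_id", "synonym", "tag")
  missing_cols <- setdiff(needed, names(clusters))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  clusters$synonym_key <- normalize_name(clusters$synonym)
  claim <- clusters |>
    dplyr::distinct(.data$cluster_id, .data$synonym_key) |>
    dplyr::count(.data$synonym_key)
  if (any(claim$n > 1)) {
    dup <- claim$synonym_key[claim$n > 1]
    abort(paste0("Synonym(s) claimed by more than one cluster: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  clusters
}

# Case-insensitive, whitespace-squished key used for all synonym matching.
normalize_name <- function(x) {
  tolower(stringr::str_squish(x))
}

#' Resolve molecule names against a synonym table
#'
#' Maps free-text molecule names to cluster identifiers. Matching is
#' case-insensitive after whitespace normalisation. Unresolvable names are
#' reported, never silently dropped.
#'
#' @param names character vector of molecule names.
#' @param clusters cluster table from [read_cluster_table()] (or any tibble
#'   with `cluster_id` and `synonym` columns; a `synonym_key` column is
#'   derived if absent).
#' @return A list with `resolved` (tibble `name`, `cluster_id`) and
#'   `unresolved` (character vector of names without a match).
#' @export
resolve_synonyms <- function(names, clusters) {
  stopifnot(is.character(names))
  if (!"synonym_key" %in% names(clusters)) {
    clusters$synonym_key <- normalize_name(clusters$synonym)
  }
  claim <- clusters |>
    dplyr::distinct(.data$cluster_id, .data$synonym_key) |>
    dplyr::count(.data$synonym_key)
  if (any(claim$n > 1)) {
    abort("Synonym table is ambiguous: a synonym maps to several clusters.")
  }
  lookup <- clusters |>
    dplyr::distinct(.data$synonym_key, .data$cluster_id)
  res <- tibble::tibble(name = names,
                        synonym_key = normalize_name(names)) |>
    dplyr::left_join(lookup, by = "synonym_key")
  list(
    resolved = res |>
      dplyr::filter(!is.na(.data$cluster_id)) |>
      dplyr::select("name", "cluster_id"),
    unresolved = res$name[is.na(res$cluster_id)]
  )
}
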