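#' Select differentially expressed records
#'
#' A record survives iff its p-value falls below the scheme's gate
#' (`p < p_cutoff`, strict) and its fold-change magnitude reaches the
#' layer-specific cutoff (`>=` by default). The result, one row per surviving
#' record ordered by study, is the per-study DE list input to vote counting.
#'
#' @param records canonical, collapsed expression records.
#' @param scheme a [threshold_scheme()].
#' @return Tibble of surviving records, arranged by `study_id`.
#' @export
filter_de <- function(records, scheme = threshold_scheme("case_study")) {
  stopifnot(inherits(scheme, "threshold_scheme"))
  missing_layers <- setdiff(unique(records$layer), names(scheme$de_fc_cutoff))
  if (length(missing_layers) > 0) {
    abort(paste0("Scheme has no fold-change cutoff for layer(s): ",
                 paste(missing_layers, collapse = ", ")))
  }
  cutoff <- scheme$de_fc_cutoff[records$layer]
  fc_ok <- if (scheme$inclusive) records$magnitude >= cutoff
           else records$magnitude > cutoff
  records |>
    dplyr::filter(.data$p_value < scheme$p_cutoff, fc_ok) |>
    dplyr::arrange(.data$study_id)
}

#' Vote-count molecules across study DE lists
#'
#' The vote of a molecule is the number of distinct study DE lists containing
#' it; molecules with at least `min_votes` votes are retained. Votes count
#' studies, not records: duplicated reports within one study contribute a
#' single vote.
#'
#' @param de_records output of [filter_de()].
#' @param min_votes minimum number of study lists (default 2).
#' @return Tibble with `molecule_id`, `votes`, `retained`, sorted by
#'   decreasing votes.
#' @export
vote_count <- function(de_records, min_votes = 2) {
  if (!is.numeric(min_votes) || min_votes < 1) {
    abort("`min_votes` must be an integer >= 1.")
  }
  de_records |>
    dplyr::distinct(.data$study_id, .data$molecule_id) |>
    dplyr::count(.data$molecule_id, name = "votes") |>
    dplyr::mutate(retained = .data$votes >= min_votes) |>
    dplyr::arrange(dplyr::desc(.data$votes), .data$molecule_id)
}

#' Regulation-direction frequency table across fold-change strata
#'
#' For every molecule and every stratum `s`, computes the percentage of its
#' study reports that are down-regulated with magnitude >= `s` (`down_pct`),
#' up-regulated with magnitude >= `s` (`up_pct`), and the remainder
#' (`nr_pct`, "not regulated" at that stratum). Percentages are over
#' `reported`, the number of distinct contributing studies, and are rounded
#' half-away-from-zero to one decimal. Input records are expected to have
#' passed the p-gate and to be collapsed to one report per (study, molecule);
#' reports below every stratum still count towards `reported`.
#'
#' @param records canonical, collapsed expression records of the retained
#'   molecules (p-gated; no fold-change gate).
#' @param strata fold-change magnitude cutoffs (default `c(1.3, 1.5, 2.0)`).
#' @param inclusive logical; compare magnitudes with `>=` (default).
#' @return A tidy tibble with one row per molecule x stratum: `molecule_id`,
#'   `layer` (if present in `records`), `reported`, `stratum`, `down_pct`,
#'   `up_pct`, `nr_pct`. Empty input yields an empty table.
#' @examples
#' recs <- tibble::tibble(
#'   study_id = c("s1", "s2"), molecule_id = "hsa-mir-144", layer = "MIR",
#'   fc = c(-1.4, -1.2), magnitude = c(1.4, 1.2), direction = "down",
#'   p_value = 0.01
#' )
#' regulation_frequency_table(recs)
#' @export
regulation_frequency_table <- function(records, strata = c(1.3, 1.5, 2.0),
                                       inclusive = TRUE) {
  if (nrow(records) == 0) {
    return(tibble::tibble(
      molecule_id = character(), reported = integer(), stratum = numeric(),
      down_pct = numeric(), up_pct = numeric(), nr_pct = numeric()
    ))
  }
  if (any(strata <= 1) || is.unsorted(strata, strictly = TRUE)) {
    abort("`strata` must be strictly increasing and each > 1.")
  }
  has_layer <- "layer" %in% names(records)
  keys <- if (has_layer) c("molecule_id", "layer") else "molecule_id"

  per_stratum <- function(s) {
    crosses <- if (inclusive) records$magnitude >= s
               else records$magnitude > s
    records |>
      dplyr::mutate(.crosses = crosses) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(
        reported = dplyr::n_distinct(.data$study_id),
        down_pct = round_half_up(
          100 * sum(.data$direction == "down" & .data$.crosses) /
            .data$reported[1], 1),
        up_pct = round_half_up(
          100 * sum(.data$direction == "up" & .data$.crosses) /
            .data$reported[1], 1),
        .groups = "drop"
      ) |>
      dplyr::mutate(stratum = s,
                    nr_pct = round_half_up(
                      100 - .data$down_pct - .data$up_pct, 1))
  }

  purrr::map(strata, per_stratum) |>
    purrr::list_rbind() |>
    dplyr::relocate(dplyr::all_of(keys), "reported", "stratum",
                    "down_pct", "up_pct", "nr_pct") |>
    dplyr::arrange(.data$molecule_id, .data$stratum)
}

#' Consensus regulation direction under the prevalence rule
#'
#' At the chosen stratum, a molecule's consensus direction is `"down"` if its
#' down-regulated report frequency reaches the prevalence threshold (60% by
#' default), `"up"` analogously, and `"discordant"` otherwise. With a
#' threshold above 50 both directions can never win at once. By default the
#' stratum read for each molecule is its layer's differential-expression
#' cutoff from `scheme` (so 2.0 for miRNA/gene, 1.5 for protein, 1.3 for
#' metabolite under the case-study preset); a single fixed `stratum` may be
#' supplied instead.
#'
#' @param freq frequency table from [regulation_frequency_table()]; must
#'   carry a `layer` column unless `stratum` is given.
#' @param scheme [threshold_scheme()] supplying per-layer strata; ignored
#'   when `stratum` is given.
#' @param threshold prevalence threshold in percent, must be > 50.
#' @param stratum optional single fold-change stratum applied to all
#'   molecules.
#' @return Tibble with `molecule_id`, `direction` (`"down"`, `"up"` or
#'   `"discordant"`), `winning_pct`, `stratum_used`, `threshold`.
#' @export
consensus_direction <- function(freq, scheme = threshold_scheme("case_study"),
                                threshold = 60, stratum = NULL) {
  if (threshold <= 50) {
    abort("`threshold` must be > 50 (ties would be ambiguous).")
  }
  if (is.null(stratum)) {
    if (!"layer" %in% names(freq)) {
      abort("`freq` needs a `layer` column when no fixed `stratum` is given.")
    }
    freq$stratum_used <- unname(scheme$de_fc_cutoff[freq$layer])
  } else {
    stopifnot(length(stratum) == 1)
    freq$stratum_used <- stratum
  }
  missing_stratum <- freq |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::summarise(ok = any(.data$stratum == .data$stratum_used),
                     .groups = "drop")
  if (!all(missing_stratum$ok)) {
    abort("The consensus stratum is absent from the frequency table's strata.")
  }
  freq |>
    dplyr::filter(.data$stratum == .data$stratum_used) |>
    dplyr::mutate(
      direction = dplyr::case_when(
        .data$down_pct >= threshold ~ "down",
        .data$up_pct >= threshold ~ "up",
        TRUE ~ "discordant"
      ),
      winning_pct = pmax(.data$down_pct, .data$up_pct),
      threshold = threshold
    ) |>
    dplyr::select("molecule_id", "direction", "winning_pct",
                  "stratum_used", "threshold")
}

#' Overall fold-change of a molecule given its consensus call
#'
#' The overall fold-change overlaid on the network is the arithmetic mean of
#' the signed canonical fold-changes of the reports agreeing with the
#' consensus direction. Discordant molecules are flagged (`NA` overall
#' fold-change), not dropped.
#'
#' @param records canonical, collapsed records of the called molecules.
#' @param calls consensus calls from [consensus_direction()].
#' @return Tibble with `molecule_id`, `direction`, `overall_fc` (`NA` when
#'   discordant), `n_agreeing`.
#' @export
overall_fold_change <- function(records, calls) {
  calls |>
    dplyr::left_join(
      records |> dplyr::select("molecule_id", "fc", "direction") |>
        dplyr::rename(report_direction = "direction"),
      by = "molecule_id"
    ) |>
    dplyr::group_by(.data$molecule_id, .data$direction) |>
    dplyr::summarise(
      overall_fc = ifelse(
        .data$direction[1] %in% c("up", "down"),
        mean(.data$fc[.data$report_direction == .data$direction[1]]),
        NA_real_
      ),
      n_agreeing = sum(.data$report_direction == .data$direction[1]),
      .groups = "drop"
    )
}

#' Run the vote-counting meta-analysis end to end
#'
#' Convenience wrapper chaining [filter_de()], [vote_count()],
#' [regulation_frequency_table()], [consensus_direction()] and
#' [overall_fold_change()] on a table of canonical, collapsed records.
#'
#' @param records canonical, collapsed expression records.
#' @param scheme a [threshold_scheme()].
#' @param min_votes minimum votes for retention (default 2).
#' @param threshold consensus prevalence threshold in percent (default 60).
#' @param stratum optional fixed consensus stratum; default reads each
#'   molecule's layer cutoff.
#' @return An object of class `omv_meta`: a list with `de`, `votes`, `freq`,
#'   `calls`, `summary` tibbles plus the parameters used.
#' @export
meta_analyse <- function(records, scheme = threshold_scheme("case_study"),
                         min_votes = 2, threshold = 60, stratum = NULL) {
  de <- filter_de(records, scheme)
  votes <- vote_count(de, min_votes)
  retained <- votes$molecule_id[votes$retained]
  reports <- records |>
    dplyr::filter(.data$molecule_id %in% retained,
                  .data$p_value < scheme$p_cutoff)
  freq <- regulation_frequency_table(reports, scheme$strata,
                                     scheme$inclusive)
  calls <- if (nrow(freq) > 0) {
    consensus_direction(freq, scheme, threshold, stratum)
  } else {
    tibble::tibble(molecule_id = character(), direction = character(),
                   winning_pct = numeric(), stratum_used = numeric(),
                   threshold = numeric())
  }
  ofc <- overall_fold_change(reports, calls)
  summary <- votes |>
    dplyr::filter(.data$retained) |>
    dplyr::left_join(calls, by = "molecule_id") |>
    dplyr::left_join(ofc |> dplyr::select(-"direction"),
                     by = "molecule_id")
  structure(
    list(de = de, votes = votes, freq = freq, calls = calls,
         summary = summary, scheme = scheme, min_votes = min_votes,
         threshold = threshold, stratum = stratum),
    class = "omv_meta"
  )
}

#' @method print omv_meta
#' @export
print.omv_meta <- function(x, ...) {
  cat("<omv_meta> vote-counting meta-analysis\n")
  cat("  scheme:", x$scheme$name, " min_votes:", x$min_votes,
      " consensus threshold:", x$threshold, "%\n")
  cat("  DE records:", nrow(x$de), " retained molecules:",
      sum(x$votes$retained), "\n")
  if (nrow(x$calls) > 0) {
    tab <- table(x$calls$direction)
    cat("  calls:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @rdname meta_analyse
#' @param x an `omv_meta` object.
#' @param ... unused.
#' @method tidy omv_meta
#' @export
tidy.omv_meta <- function(x, ...) {
  x$summary
}

#' @rdname meta_analyse
#' @method glance omv_meta
#' @export
glance.omv_meta <- function(x, ...) {
  tibble::tibble(
    n_de_records = nrow(x$de),
    n_retained = sum(x$votes$retained),
    n_down = sum(x$calls$direction == "down"),
    n_up = sum(x$calls$direction == "up"),
    n_discordant = sum(x$calls$direction == "discordant"),
    scheme = x$scheme$name,
    min_votes = x$min_votes,
    threshold = x$threshold
  )
}

#' Plot a meta-analysis result
#'
#' Shows the winning consensus frequency per molecule, coloured by call
#' direction.
#'
#' @param object an `omv_meta` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot omv_meta
#' @export
autoplot.omv_meta <- function(object, ...) {
  calls <- object$calls
  ggplot2::ggplot(calls, ggplot2::aes(
    x = stats::reorder(.data$molecule_id, .data$winning_pct),
    y = .data$winning_pct, fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "winning report frequency (%)",
                  fill = "consensus") +
    ggplot2::theme_minimal()
}
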