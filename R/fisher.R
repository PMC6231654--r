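#' Combine p-values by Fisher's method
#'
#' Combines k independent p-values via the statistic X = -2 * sum(log(p)),
#' referred to a chi-square distribution with 2k degrees of freedom
#' (upper tail). Used when a study reports the same molecule several times:
#' the redundant entries' p-values are combined into one.
#'
#' @param p_values numeric vector of p-values, each in (0, 1]; must be
#'   non-empty.
#' @return A single combined p-value in (0, 1]. For a single input the input
#'   is returned unchanged; the result is invariant under permutation.
#' @examples
#' fisher_combine(c(0.05, 0.05)) # ~0.0175
#' fisher_combine(0.2)           # 0.2
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) == 0) abort("`p_values` must be non-empty.")
  if (!is.numeric(p_values) || anyNA(p_values)) {
    abort("`p_values` must be numeric with no missing values.")
  }
  if (any(p_values <= 0 | p_values > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  x <- -2 * sum(log(p_values))
  stats::pchisq(x, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Collapse redundant within-study records of a molecule
#'
#' A study sometimes reports the same molecule more than once (e.g. several
#' peptides or adducts mapping to one cluster). Redundant entries are combined
#' by averaging their expression values and combining their p-values with
#' Fisher's method. Averaging is on the linear signed fold-change scale by
#' default; `fc_average = "log2"` averages signed log2 fold-changes instead
#' and back-transforms.
#'
#' Groups whose reports disagree in direction may average to a fold-change of
#' magnitude below 1; such a mean is reported as direction `"none"`
#' (magnitude 1) with a warning, since conflicting within-study reports carry
#' no usable direction.
#'
#' @param records data frame of canonical expression records with columns
#'   `study_id`, `molecule_id`, `layer`, `fc`, `magnitude`, `direction`,
#'   `p_value` (see [canonicalize_records()]).
#' @param fc_average `"linear"` (default) or `"log2"`.
#' @return A tibble with one row per (study, molecule): the collapsed records.
#'   Other columns (e.g. `compartment`, `species`) keep their first value.
#' @export
collapse_records <- function(records, fc_average = c("linear", "log2")) {
  fc_average <- match.arg(fc_average)
  needed <- c("study_id", "molecule_id", "layer", "fc", "p_value")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("`records` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(records$p_value <= 0 | records$p_value > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  layer_chk <- records |>
    dplyr::distinct(.data$study_id, .data$molecule_id, .data$layer) |>
    dplyr::count(.data$study_id, .data$molecule_id)
  if (any(layer_chk$n > 1)) {
    abort("Inconsistent omics layer within a (study, molecule) group.")
  }

  mean_fc <- function(v) {
    if (fc_average == "log2") {
      log2_to_signed_fc(mean(signed_fc_to_log2(v)))
    } else {
      mean(v)
    }
  }

  other <- setdiff(names(records),
                   c("study_id", "molecule_id", "layer", "fc", "magnitude",
                     "direction", "p_value"))
  out <- records |>
    dplyr::group_by(.data$study_id, .data$molecule_id, .data$layer) |>
    dplyr::summarise(
      fc = mean_fc(.data$fc),
      p_value = fisher_combine(.data$p_value),
      dplyr::across(dplyr::all_of(other), dplyr::first),
      .groups = "drop"
    )

  sub_unit <- abs(out$fc) < 1
  if (any(sub_unit)) {
    warn(sprintf(
      "%d collapsed group(s) had conflicting directions averaging below |1|; reported as direction 'none'.",
      sum(sub_unit)
    ))
    out$fc[sub_unit] <- 1
  }
  out$magnitude <- abs(out$fc)
  out$direction <- ifelse(out$magnitude == 1, "none",
                          ifelse(out$fc > 0, "up", "down"))
  dplyr::relocate(out, "study_id", "molecule_id", "layer", "fc",
                  "magnitude", "direction", "p_value")
}
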