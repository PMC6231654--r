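#' Canonicalize fold-changes to the signed convention
#'
#' Source tables report fold-changes in two dialects: *signed* (down-regulation
#' as a negative value, e.g. -1.4 for a 1.4-fold decrease) and *ratio*
#' (down-regulation as a fraction, e.g. 0.5 for a 2-fold decrease). This
#' function maps either dialect onto the canonical signed representation used
#' everywhere downstream: a signed `value`, a `magnitude` >= 1, and a
#' `direction` in `"up"`, `"down"`, `"none"` (`"none"` only when the magnitude
#' is exactly 1).
#'
#' Under the signed dialect a positive fractional input (0 < raw < 1) is read
#' as a ratio-style decrease (magnitude `1/raw`), and a negative fractional
#' input likewise as a decrease of magnitude `1/|raw|`: both notations signal
#' depletion, and canonicalization is idempotent on its own output.
#'
#' @param raw numeric vector of reported fold-changes. Zero is invalid in
#'   either dialect; negative values are invalid under `"ratio"`.
#' @param dialect `"signed"` or `"ratio"`.
#' @return A tibble with columns `value` (canonical signed fold-change),
#'   `magnitude` (>= 1) and `direction` (`"up"`, `"down"` or `"none"`),
#'   one row per element of `raw`.
#' @examples
#' canonicalize_fc(c(-1.4, 2), "signed")
#' canonicalize_fc(0.5, "ratio") # 2-fold decrease
#' @export
canonicalize_fc <- function(raw, dialect = c("signed", "ratio")) {
  dialect <- match.arg(dialect)
  if (!is.numeric(raw) || length(raw) == 0) {
    abort("`raw` must be a non-empty numeric vector.")
  }
  if (anyNA(raw)) abort("`raw` contains missing values.")
  if (any(raw == 0)) abort("Fold-change of 0 is invalid in either dialect.")
  if (dialect == "ratio" && any(raw < 0)) {
    abort("Negative values are invalid under the ratio dialect.")
  }

  if (dialect == "ratio") {
    magnitude <- ifelse(raw < 1, 1 / raw, raw)
    direction <- ifelse(raw > 1, "up", ifelse(raw < 1, "down", "none"))
  } else {
    mag_abs <- abs(raw)
    magnitude <- ifelse(mag_abs < 1, 1 / mag_abs, mag_abs)
    direction <- ifelse(
      mag_abs == 1, "none",
      # fractional |raw| < 1 always signals depletion; otherwise the sign rules
      ifelse(mag_abs < 1, "down", ifelse(raw > 0, "up", "down"))
    )
  }
  value <- ifelse(direction == "down", -magnitude, magnitude)
  tibble::tibble(value = value, magnitude = magnitude, direction = direction)
}

#' Canonicalize the fold-change column of a record table
#'
#' Applies [canonicalize_fc()] to the `fc` column and replaces it with the
#' canonical `fc`, `magnitude` and `direction` columns.
#'
#' @param records data frame with at least an `fc` column.
#' @param dialect fold-change dialect of the `fc` column.
#' @return `records` as a tibble with canonical `fc`, `magnitude`,
#'   `direction`.
#' @export
canonicalize_records <- function(records, dialect = c("signed", "ratio")) {
  stopifnot(is.data.frame(records), "fc" %in% names(records))
  canon <- canonicalize_fc(records$fc, dialect)
  records <- tibble::as_tibble(records)
  records$fc <- canon$value
  records$magnitude <- canon$magnitude
  records$direction <- canon$direction
  records
}

# Signed linear fold-change -> signed log2 fold-change (down negative).
signed_fc_to_log2 <- function(value) {
  sign(value) * log2(abs(value))
}

# Inverse of signed_fc_to_log2.
log2_to_signed_fc <- function(l2) {
  ifelse(l2 < 0, -(2^(-l2)), 2^(l2))
}
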