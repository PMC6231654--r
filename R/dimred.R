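#' Build the molecule x study log2 fold-change matrix
#'
#' Rows are molecules (variables), columns are studies (samples); cells hold
#' the signed log2 fold-change (down-regulation negative). Molecules reported
#' in fewer than `min_reports` independent studies are dropped; missing
#' (study, molecule) cells are imputed as 0 and flagged in a parallel logical
#' mask.
#'
#' @param records canonical, collapsed expression records.
#' @param min_reports minimum number of contributing studies per molecule
#'   (default 3).
#' @return An object of class `de_matrix`: list with `matrix` (molecules x
#'   studies, log2 scale), `mask` (TRUE where imputed), `min_reports`.
#' @export
build_de_matrix <- function(records, min_reports = 3) {
  studies <- sort(unique(records$study_id))
  if (length(studies) < 2) {
    abort("At least 2 studies are required to build a DE matrix.")
  }
  dup <- records |>
    dplyr::count(.data$molecule_id, .data$study_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("Records must be collapsed to one report per (study, molecule).")
  }
  kept <- records |>
    dplyr::count(.data$molecule_id, name = "n_reports") |>
    dplyr::filter(.data$n_reports >= min_reports)
  rec <- records |>
    dplyr::semi_join(kept, by = "molecule_id") |>
    dplyr::mutate(l2 = signed_fc_to_log2(.data$fc))
  molecules <- sort(unique(rec$molecule_id))
  if (length(molecules) == 0) {
    abort("No molecule reaches `min_reports` studies.")
  }
  m <- matrix(0, nrow = length(molecules), ncol = length(studies),
              dimnames = list(molecules, studies))
  mask <- matrix(TRUE, nrow = length(molecules), ncol = length(studies),
                 dimnames = list(molecules, studies))
  idx <- cbind(match(rec$molecule_id, molecules),
               match(rec$study_id, studies))
  m[idx] <- rec$l2
  mask[idx] <- FALSE
  structure(list(matrix = m, mask = mask, min_reports = min_reports),
            class = "de_matrix")
}

#' @export
print.de_matrix <- function(x, ...) {
  cat("<de_matrix>", nrow(x$matrix), "molecules x", ncol(x$matrix),
      "studies;", sum(x$mask), "cells imputed as 0\n")
  invisible(x)
}

#' Export / re-import a DE matrix as TSV with a sidecar mask
#'
#' @param x a `de_matrix`.
#' @param path path of the matrix TSV; the mask goes to `<path>.mask`.
#' @return Invisibly, `path`.
#' @export
write_de_matrix <- function(x, path) {
  stopifnot(inherits(x, "de_matrix"))
  tb <- tibble::as_tibble(x$matrix, rownames = "molecule_id")
  readr::write_tsv(tb, path)
  mk <- tibble::as_tibble(x$mask, rownames = "molecule_id")
  readr::write_tsv(mk, paste0(path, ".mask"))
  invisible(path)
}

#' @rdname write_de_matrix
#' @param min_reports the `min_reports` recorded with the matrix.
#' @export
read_de_matrix <- function(path, min_reports = 3) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tb[, -1])
  rownames(m) <- tb$molecule_id
  mk <- readr::read_tsv(paste0(path, ".mask"), show_col_types = FALSE)
  mask <- as.matrix(mk[, -1])
  rownames(mask) <- mk$molecule_id
  structure(list(matrix = m, mask = mask, min_reports = min_reports),
            class = "de_matrix")
}

#' Principal component analysis of the DE matrix
#'
#' Studies are the samples: PCA runs on the study x molecule data after
#' column (molecule) centering. Data are not standardised by default
#' (covariance PCA); `standardize = TRUE` scales molecules to unit variance
#' first (zero-variance molecules are dropped with a message in that case).
#'
#' @param x a `de_matrix` or a numeric samples-by-variables matrix.
#' @param standardize logical (default `FALSE`).
#' @return An object of class `omv_pca`: list with `scores` (samples x
#'   components), `loadings` (variables x components), `variance_fraction`.
#' @export
run_pca <- function(x, standardize = FALSE) {
  m <- if (inherits(x, "de_matrix")) t(x$matrix) else as.matrix(x)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("PCA needs at least 2 samples and 2 variables.")
  }
  if (standardize) {
    v <- apply(m, 2, var)
    if (any(v == 0)) {
      inform(sprintf("%d zero-variance variable(s) dropped.", sum(v == 0)))
      m <- m[, v > 0, drop = FALSE]
    }
  }
  if (sum(apply(m, 2, var)) == 0) {
    abort("Matrix has zero total variance; PCA is degenerate.")
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = standardize)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(scores = fit$x, loadings = fit$rotation, variance_fraction = vf,
         standardize = standardize),
    class = "omv_pca"
  )
}

#' @method print omv_pca
#' @export
print.omv_pca <- function(x, ...) {
  cat("<omv_pca>", nrow(x$scores), "samples,", nrow(x$loadings),
      "variables\n")
  k <- min(3, length(x$variance_fraction))
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k),
                    100 * x$variance_fraction[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @rdname run_pca
#' @param x an `omv_pca` object (for the tidier).
#' @param ... unused.
#' @method tidy omv_pca
#' @export
tidy.omv_pca <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "component",
                        values_to = "score")
}

#' @rdname run_pca
#' @method glance omv_pca
#' @export
glance.omv_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_variables = nrow(x$loadings),
    pc1_fraction = x$variance_fraction[1],
    pc2_fraction = if (length(x$variance_fraction) > 1) {
      x$variance_fraction[2]
    } else NA_real_,
    standardize = x$standardize
  )
}

#' @rdname run_pca
#' @param object an `omv_pca` object.
#' @method autoplot omv_pca
#' @export
autoplot.omv_pca <- function(object, ...) {
  sc <- tibble::as_tibble(object$scores, rownames = "sample")
  vf <- object$variance_fraction
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                   label = .data$sample)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * vf[2])
    ) +
    ggplot2::theme_minimal()
}

#' Non-metric multidimensional scaling of study profiles
#'
#' Embeds the studies in 2 or 3 dimensions by minimising Kruskal stress-1
#' over monotone-regressed disparities of the Euclidean distances between
#' study profiles (or of a supplied distance matrix), taking the best of
#' `n_restarts` random starts. The run is seeded and reproducible.
#'
#' @param x a `de_matrix`, a samples-by-variables matrix, or a `dist`.
#' @param dims embedding dimension, 2 or 3.
#' @param seed integer seed.
#' @param n_restarts number of random restarts (default 20).
#' @return An object of class `omv_nmds`: list with `points` (coordinates),
#'   `stress`, `dims`, `seed`, `n_restarts`.
#' @export
run_nmds <- function(x, dims = 2, seed = 1L, n_restarts = 20) {
  if (!dims %in% c(2, 3)) abort("`dims` must be 2 or 3.")
  d <- if (inherits(x, "dist")) {
    x
  } else if (inherits(x, "de_matrix")) {
    stats::dist(t(x$matrix))
  } else {
    stats::dist(as.matrix(x))
  }
  n <- attr(d, "Size")
  if (n < 3) abort("NMDS needs at least 3 points.")
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = dims, trymax = n_restarts, trace = 0,
                        autotransform = FALSE, wascores = FALSE,
                        weakties = TRUE)
  structure(
    list(points = fit$points, stress = fit$stress, dims = dims,
         seed = seed, n_restarts = n_restarts),
    class = "omv_nmds"
  )
}

#' @method print omv_nmds
#' @export
print.omv_nmds <- function(x, ...) {
  cat("<omv_nmds>", nrow(x$points), "points in", x$dims,
      "dimensions; stress =", signif(x$stress, 4), "\n")
  invisible(x)
}

#' @rdname run_nmds
#' @param object an `omv_nmds` object.
#' @param ... unused.
#' @method autoplot omv_nmds
#' @export
autoplot.omv_nmds <- function(object, ...) {
  pts <- tibble::as_tibble(object$points, rownames = "sample")
  ggplot2::ggplot(pts, ggplot2::aes(.data$MDS1, .data$MDS2,
                                    label = .data$sample)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      caption = sprintf("stress = %.3f", object$stress)
    ) +
    ggplot2::theme_minimal()
}
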