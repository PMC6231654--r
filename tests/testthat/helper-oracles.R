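# Independent oracles used to cross-check the package's implementations.
# These are written against the underlying mathematics, not the package code.

# Chi-square upper tail at even degrees of freedom 2k via the closed-form
# Erlang survival function: P(X >= x) = exp(-x/2) * sum_{i=0}^{k-1} (x/2)^i/i!
chisq_upper_tail_oracle <- function(x, k) {
  h <- x / 2
  exp(-h) * sum(h^seq(0, k - 1) / factorial(seq(0, k - 1)))
}

fisher_oracle <- function(p) {
  chisq_upper_tail_oracle(-2 * sum(log(p)), length(p))
}

# Hypergeometric upper tail by exhaustive enumeration of all draws.
hyper_upper_tail_oracle <- function(universe_size, set_size, query_size,
                                    min_hits) {
  universe <- seq_len(universe_size)
  in_set <- universe <= set_size
  draws <- utils::combn(universe_size, query_size)
  hits <- colSums(matrix(in_set[draws], nrow = query_size))
  mean(hits >= min_hits)
}

# Build a canonical record tibble from parallel vectors (p defaults to 0.01).
make_records <- function(study_id, molecule_id, layer, fc, p_value = 0.01,
                         dialect = "signed") {
  tb <- tibble::tibble(
    study_id = study_id, molecule_id = molecule_id, layer = layer,
    fc = fc, p_value = p_value,
    compartment = "plasma", species = "Homo sapiens"
  )
  canonicalize_records(tb, dialect)
}

# Reconstruct per-study reports consistent with a frequency-table row set:
# counts per direction and magnitude bucket recovered from the stratum
# percentages, magnitudes placed mid-bucket, one study per report.
reconstruct_reports <- function(fixture_wide) {
  purrr::pmap(fixture_wide, function(molecule, layer, reported,
                                     down13, down15, down20,
                                     up13, up15, up20, ...) {
    n <- reported
    cnt <- function(pct) round(pct * n / 100)
    rows <- list()
    for (d in c("down", "up")) {
      p13 <- cnt(get(paste0(d, "13")))
      p15 <- cnt(get(paste0(d, "15")))
      p20 <- cnt(get(paste0(d, "20")))
      sgn <- if (d == "down") -1 else 1
      mags <- c(rep(2.5, p20), rep(1.6, p15 - p20), rep(1.4, p13 - p15))
      if (length(mags) > 0) {
        rows[[d]] <- sgn * mags
      }
    }
    fc <- unlist(rows, use.names = FALSE)
    n_sub <- n - length(fc)
    if (n_sub > 0) fc <- c(fc, rep(c(-1.1, 1.1), length.out = n_sub))
    tibble::tibble(
      study_id = sprintf("S%02d", seq_len(n)),
      molecule_id = molecule, layer = layer, fc = fc, p_value = 0.01
    )
  }) |> purrr::list_rbind() |>
    canonicalize_records("signed")
}

# Fully independent brute-force meta-analysis on raw records (plain loops).
brute_force_meta <- function(records, p_cut, fc_cut_by_layer, min_votes,
                             strata, threshold) {
  studies <- unique(records$study_id)
  # per-study DE lists
  de_lists <- lapply(studies, function(s) {
    out <- character()
    for (i in seq_len(nrow(records))) {
      r <- records[i, ]
      if (r$study_id != s) next
      if (r$p_value < p_cut && r$magnitude >= fc_cut_by_layer[[r$layer]]) {
        out <- c(out, r$molecule_id)
      }
    }
    unique(out)
  })
  votes <- table(unlist(de_lists))
  retained <- names(votes)[votes >= min_votes]
  freq <- list()
  calls <- list()
  for (m in retained) {
    sub <- records[records$molecule_id == m & records$p_value < p_cut, ]
    n <- length(unique(sub$study_id))
    layer <- sub$layer[1]
    for (s in strata) {
      dn <- 0; up <- 0
      for (i in seq_len(nrow(sub))) {
        if (sub$magnitude[i] >= s) {
          if (sub$direction[i] == "down") dn <- dn + 1
          if (sub$direction[i] == "up") up <- up + 1
        }
      }
      dn_pct <- floor(abs(100 * dn / n) * 10 + 0.5) / 10
      up_pct <- floor(abs(100 * up / n) * 10 + 0.5) / 10
      freq[[paste(m, s)]] <- data.frame(
        molecule_id = m, stratum = s, reported = n,
        down_pct = dn_pct, up_pct = up_pct,
        nr_pct = 100 - dn_pct - up_pct
      )
      if (s == fc_cut_by_layer[[layer]]) {
        dir <- if (dn_pct >= threshold) "down"
               else if (up_pct >= threshold) "up" else "discordant"
        calls[[m]] <- data.frame(molecule_id = m, direction = dir)
      }
    }
  }
  list(
    votes = votes,
    freq = do.call(rbind, unname(freq)),
    calls = do.call(rbind, unname(calls))
  )
}
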