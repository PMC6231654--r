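test_that("filter_de applies the p-gate and layer-specific cutoffs", {
  recs <- make_records(
    study_id = c("s1", "s2", "s3", "s4"),
    molecule_id = c("p1", "m1", "p2", "p3"),
    layer = c("PRO", "MET", "PRO", "PRO"),
    fc = c(1.4, -1.35, 1.5, 3.0),
    p_value = c(0.01, 0.03, 0.04, 0.06)
  )
  de <- filter_de(recs, threshold_scheme("case_study"))
  # PRO at 1.4 misses the 1.5 cutoff; MET 1.35 passes 1.3; PRO 1.5 passes
  # inclusively; p = 0.06 fails the gate regardless of |FC| = 3
  expect_setequal(de$molecule_id, c("m1", "p2"))

  gene <- make_records("s1", "g1", "GENE", 2.5, 0.01)
  custom <- threshold_scheme(de_fc_cutoff = c(PRO = 1.5))
  expect_error(filter_de(gene, custom), "no fold-change cutoff")
})

test_that("switching case_study to curation only grows PRO DE lists", {
  set.seed(5)
  corpus <- generate_corpus(corpus_config(seed = 5))
  collapsed <- collapse_records(corpus$records)
  de_cs <- filter_de(collapsed, threshold_scheme("case_study"))
  de_cu <- filter_de(collapsed, threshold_scheme("curation"))
  key <- function(d) paste(d$study_id, d$molecule_id)
  expect_true(all(key(de_cs) %in% key(de_cu)))
  pro_cs <- de_cs[de_cs$layer == "PRO", ]
  pro_cu <- de_cu[de_cu$layer == "PRO", ]
  expect_gte(nrow(pro_cu), nrow(pro_cs))
  # non-PRO layers are untouched by the scheme switch
  expect_setequal(key(de_cs[de_cs$layer != "PRO", ]),
                  key(de_cu[de_cu$layer != "PRO", ]))
})

test_that("vote_count counts studies, not records", {
  de <- make_records(
    study_id = c("s1", "s2", "s3", "s4", "s5", "s1"),
    molecule_id = c("m1", "m1", "m1", "m1", "m1", "m2"),
    layer = "MET", fc = 2.0
  )
  votes <- vote_count(de, min_votes = 2)
  expect_equal(votes$votes[votes$molecule_id == "m1"], 5)
  expect_false(votes$retained[votes$molecule_id == "m2"])
  # a duplicated within-study report still yields one vote
  dup <- dplyr::bind_rows(de, de[1, ])
  expect_equal(vote_count(dup)$votes[1], 5)
  expect_error(vote_count(de, min_votes = 0), "min_votes")
})

test_that("regulation frequencies reproduce worked report-table rows", {
  # miRNA reported twice, FCs -1.4 / -1.2: down 50% only at stratum 1.3
  mir <- make_records(c("s1", "s2"), "hsa-mir-144", "MIR", c(-1.4, -1.2))
  f <- regulation_frequency_table(mir)
  expect_equal(f$down_pct, c(50, 0, 0))
  expect_equal(f$up_pct, c(0, 0, 0))
  expect_equal(f$nr_pct, c(50, 100, 100))
  expect_equal(unique(f$reported), 2L)

  # protein reported seven times (APOB-like row)
  apob <- make_records(sprintf("s%d", 1:7), "APOB", "PRO",
                       c(-1.6, -1.4, -1.25, -1.1, -1.0, 1.1, 1.2))
  fa <- regulation_frequency_table(apob)
  expect_equal(fa$down_pct[fa$stratum == 1.3], 28.6)
  expect_equal(fa$down_pct[fa$stratum == 1.5], 14.3)
  expect_equal(fa$down_pct[fa$stratum == 2.0], 0)
  expect_equal(unique(fa$reported), 7L)

  # nothing crosses any stratum
  flat <- make_records(c("s1", "s2"), "m", "MET", c(1.0, -1.0))
  ff <- regulation_frequency_table(flat)
  expect_equal(ff$nr_pct, c(100, 100, 100))

  expect_equal(nrow(regulation_frequency_table(mir[0, ])), 0)
})

test_that("frequency rows are closed and monotone across strata", {
  set.seed(9)
  corpus <- generate_corpus(corpus_config(seed = 9))
  reports <- collapse_records(corpus$records) |>
    dplyr::filter(p_value < 0.05)
  f <- regulation_frequency_table(reports)
  expect_true(all(abs(f$down_pct + f$up_pct + f$nr_pct - 100) <= 0.2))
  by_mol <- split(f[order(f$stratum), ], f$molecule_id[order(f$stratum)])
  for (rows in by_mol) {
    expect_true(all(diff(rows$down_pct) <= 0))
    expect_true(all(diff(rows$up_pct) <= 0))
    expect_true(all(diff(rows$nr_pct) >= 0))
  }
})

test_that("consensus direction follows the 60% prevalence rule", {
  # TMSB4X-like: 80% up at its layer stratum
  f <- regulation_frequency_table(
    make_records(sprintf("s%d", 1:5), "TMSB4X", "PRO",
                 c(1.6, 1.7, 1.8, 1.9, -1.6))
  )
  call <- consensus_direction(f)
  expect_equal(call$direction, "up")
  expect_equal(call$winning_pct, 80)
  expect_equal(call$stratum_used, 1.5)

  # 50/50 split is discordant under a 60% threshold
  split50 <- regulation_frequency_table(
    make_records(c("s1", "s2"), "m", "MET", c(1.5, -1.5))
  )
  expect_equal(consensus_direction(split50)$direction, "discordant")

  # unanimity
  unan <- regulation_frequency_table(
    make_records(c("s1", "s2"), "m", "MET", c(-1.5, -1.6))
  )
  expect_equal(consensus_direction(unan)$direction, "down")

  expect_error(consensus_direction(f, threshold = 50), "> 50")
  expect_error(consensus_direction(f, stratum = 1.7), "absent")
})

test_that("overall fold-change averages direction-agreeing reports", {
  recs <- make_records(c("s1", "s2"), "m", "MET", c(-1.6, -1.4))
  calls <- consensus_direction(regulation_frequency_table(recs))
  ofc <- overall_fold_change(recs, calls)
  expect_equal(ofc$overall_fc, -1.5)

  single <- make_records("s1", "m", "MET", 1.8)
  call1 <- tibble::tibble(molecule_id = "m", direction = "up",
                          winning_pct = 100, stratum_used = 1.3,
                          threshold = 60)
  expect_equal(overall_fold_change(single, call1)$overall_fc, 1.8)

  disc <- tibble::tibble(molecule_id = "m", direction = "discordant",
                         winning_pct = 50, stratum_used = 1.3,
                         threshold = 60)
  out <- overall_fold_change(recs, disc)
  expect_equal(nrow(out), 1) # flagged, not dropped
  expect_true(is.na(out$overall_fc))
})

test_that("the pipeline matches a brute-force enumeration on small corpora", {
  set.seed(21)
  for (rep in 1:3) {
    n_st <- sample(3:5, 1)
    n_mol <- sample(5:10, 1)
    grid <- expand.grid(study_id = sprintf("s%d", 1:n_st),
                        molecule_id = sprintf("m%d", 1:n_mol),
                        stringsAsFactors = FALSE)
    keep <- runif(nrow(grid)) < 0.7
    grid <- grid[keep, ]
    layer <- setNames(sample(c("MIR", "PRO", "MET"), n_mol, replace = TRUE),
                      sprintf("m%d", 1:n_mol))
    recs <- make_records(
      grid$study_id, grid$molecule_id, unname(layer[grid$molecule_id]),
      fc = sample(c(-2.5, -1.6, -1.4, -1.1, 1.1, 1.4, 1.6, 2.5),
                  nrow(grid), replace = TRUE),
      p_value = sample(c(0.01, 0.03, 0.2), nrow(grid), replace = TRUE)
    )
    scheme <- threshold_scheme("case_study")
    fit <- meta_analyse(recs, scheme)
    oracle <- brute_force_meta(
      recs, scheme$p_cutoff, as.list(scheme$de_fc_cutoff),
      min_votes = 2, strata = scheme$strata, threshold = 60
    )
    votes <- fit$votes[fit$votes$votes > 0, ]
    expect_equal(setNames(votes$votes, votes$molecule_id)[order(votes$molecule_id)],
                 c(oracle$votes)[order(names(oracle$votes))],
                 ignore_attr = TRUE)
    if (!is.null(oracle$freq)) {
      merged <- merge(fit$freq, oracle$freq,
                      by = c("molecule_id", "stratum"))
      expect_equal(merged$down_pct.x, merged$down_pct.y)
      expect_equal(merged$up_pct.x, merged$up_pct.y)
      expect_equal(merged$reported.x, merged$reported.y)
      expect_equal(nrow(merged), nrow(fit$freq))
    }
    if (!is.null(oracle$calls)) {
      mc <- merge(fit$calls, oracle$calls, by = "molecule_id")
      expect_equal(mc$direction.x, mc$direction.y)
      expect_equal(nrow(mc), nrow(fit$calls))
    }
  }
})

test_that("meta_analyse tidiers and plot work", {
  set.seed(2)
  corpus <- generate_corpus(corpus_config(seed = 2))
  fit <- meta_analyse(collapse_records(corpus$records))
  td <- tidy(fit)
  expect_true(all(c("molecule_id", "votes", "direction", "overall_fc")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_retained, sum(fit$votes$retained))
  expect_s3_class(autoplot(fit), "ggplot")
})
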