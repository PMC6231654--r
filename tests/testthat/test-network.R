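edges_fixture <- function() {
  tibble::tibble(
    source = c("APOB", "APOB", "APOA1", "mir1", "mir2", "mir3",
               "GENE1", "ENZ1", "RX1"),
    target = c("APOA1", "APOA1", "ALB", "APOB", "APOA1", "ALB",
               "ENZ1", "RX1", "CMP1"),
    kind = c("ppi", "ppi", "ppi", "mir_target_predicted",
             "mir_target_validated", "mir_target_predicted",
             "gene_enzyme", "enzyme_reaction", "reaction_compound"),
    confidence = c(0.8, 0.9, 0.69, NA, NA, NA, NA, NA, NA)
  )
}

calls_fixture <- function() {
  tibble::tibble(
    molecule_id = c("APOB", "APOA1", "ALB", "mir1", "mir2", "mir3"),
    direction = c("up", "down", "discordant", "down", "down", "up"),
    winning_pct = c(80, 70, 50, 100, 100, 100),
    stratum_used = 2, threshold = 60
  )
}

test_that("edge pooling deduplicates keeping the best confidence", {
  pooled <- load_edges(edges_fixture())
  ppi <- pooled[pooled$kind == "ppi" & pooled$source == "APOB", ]
  expect_equal(nrow(ppi), 1)
  expect_equal(ppi$confidence, 0.9)
  report <- attr(pooled, "load_report")
  expect_equal(report$n_deduplicated, 1)
  expect_error(load_edges(tibble::tibble(source = "a", target = "b",
                                         kind = "friendship")),
               "Unknown edge kind")
})

test_that("edges resolve through the synonym table with skips logged", {
  clusters <- tibble::tibble(
    cluster_id = c("C_APOB", "C_APOA1"),
    synonym = c("APOB", "APOA1"), tag = "TP"
  )
  edges <- tibble::tibble(
    source = c("apob", "APOB"), target = c("APOA1", "mystery"),
    kind = "ppi", confidence = c(0.8, 0.9)
  )
  expect_message(pooled <- load_edges(edges, clusters), "skipped")
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$source, "C_APOB")
  expect_equal(attr(pooled, "load_report")$n_skipped, 1)
})

test_that("edge files parse in both formats and enforce ppi confidence", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "edges.tsv")
  readr::write_tsv(tibble::tibble(source = "A", target = "B",
                                  confidence = 0.8), tsv)
  e <- read_edge_file(tsv, "ppi")
  expect_equal(e$confidence, 0.8)

  sif <- file.path(dir, "edges.sif")
  writeLines("A\tpp\tB", sif)
  # a SIF ppi line without a confidence column is rejected
  expect_error(read_edge_file(sif, "ppi", format = "sif"), "confidence")
  # but is fine for kinds that do not need confidence
  e2 <- read_edge_file(sif, "tf_target", format = "sif")
  expect_equal(e2$source, "A")
  expect_error(read_edge_file(tsv, "hyperedge"), "Unknown edge kind")
})

test_that("ppi confidence filter is inclusive at 0.7 and idempotent", {
  edges <- tibble::tibble(
    source = c("a", "b", "c", "d"), target = c("x", "y", "z", "w"),
    kind = c("ppi", "ppi", "ppi", "tf_target"),
    confidence = c(0.69, 0.70, 0.90, NA)
  )
  kept <- filter_ppi(edges)
  expect_setequal(kept$source, c("b", "c", "d"))
  expect_equal(filter_ppi(kept), kept)
})

test_that("inverse-regulation filter keeps only opposing miRNA-target pairs", {
  pooled <- load_edges(edges_fixture()) |> filter_ppi()
  out <- inverse_regulation_filter(pooled, calls_fixture())
  mir <- out[grepl("mir_target", out$kind), ]
  # mir1(down)->APOB(up): kept; mir2(down)->APOA1(down): same direction;
  # mir3(up)->ALB(discordant): dropped with reason
  expect_equal(mir$source, "mir1")
  reasons <- attr(out, "drop_report")
  expect_setequal(reasons$reason,
                  c("same direction", "endpoint discordant"))
  # exhaustive check of the output contract
  dirs <- setNames(calls_fixture()$direction, calls_fixture()$molecule_id)
  expect_true(all(
    (dirs[mir$source] == "down" & dirs[mir$target] == "up") |
      (dirs[mir$source] == "up" & dirs[mir$target] == "down")
  ))
  # optional magnitude floor on the miRNA endpoint
  overall <- tibble::tibble(molecule_id = c("mir1"), overall_fc = -1.2)
  out2 <- inverse_regulation_filter(pooled, calls_fixture(),
                                    overall = overall, min_magnitude = 1.5)
  expect_equal(sum(grepl("mir_target", out2$kind)), 0)
})

test_that("network assembly types nodes, attaches expression, prunes", {
  calls <- calls_fixture() |>
    dplyr::mutate(layer = c("PRO", "PRO", "PRO", "MIR", "MIR", "MIR"))
  overall <- tibble::tibble(
    molecule_id = calls$molecule_id,
    overall_fc = c(2.1, -1.8, NA, -2.2, -2.0, 2.4)
  )
  votes <- tibble::tibble(molecule_id = calls$molecule_id,
                          votes = c(7, 5, 2, 2, 2, 2), retained = TRUE)
  pooled <- load_edges(edges_fixture()) |>
    filter_ppi() |>
    inverse_regulation_filter(calls)
  net <- assemble_network(calls, overall, votes, pooled)
  expect_s3_class(net, "hetero_network")
  kinds <- setNames(net$nodes$kind, net$nodes$id)
  expect_equal(unname(kinds["mir1"]), "mirna")
  expect_equal(unname(kinds["APOB"]), "gene_protein")
  expect_equal(unname(kinds["RX1"]), "reaction")
  expect_equal(unname(kinds["CMP1"]), "compound")
  # provenance: queries vs edge-inferred nodes
  prov <- setNames(net$nodes$provenance, net$nodes$id)
  expect_equal(unname(prov["APOB"]), "query")
  expect_equal(unname(prov["ENZ1"]), "inferred")
  # expression annotation travels onto query nodes
  nd <- net$nodes[net$nodes$id == "APOB", ]
  expect_equal(nd$direction, "up")
  expect_equal(nd$overall_fc, 2.1)
  expect_equal(nd$report_count, 7)
  # every query node carries a direction or the discordant flag
  q <- net$nodes[net$nodes$provenance == "query", ]
  expect_true(all(q$direction %in% c("up", "down", "discordant")))
  # mir2 lost its only edge to the inverse filter but stays (query);
  # pruning removes isolated inferred nodes only
  expect_true("mir2" %in% net$nodes$id)
  deg <- igraph::degree(net$graph)
  inferred <- net$nodes$id[net$nodes$provenance == "inferred"]
  expect_true(all(deg[inferred] > 0))
})

test_that("gda rows contextualise the network with disease nodes", {
  calls <- calls_fixture()[1:2, ] |> dplyr::mutate(layer = "PRO")
  overall <- tibble::tibble(molecule_id = calls$molecule_id,
                            overall_fc = c(2.1, -1.8))
  votes <- tibble::tibble(molecule_id = calls$molecule_id,
                          votes = c(7, 5), retained = TRUE)
  edges <- tibble::tibble(source = "APOB", target = "APOA1", kind = "ppi",
                          confidence = 0.9)
  gda <- tibble::tibble(gene = c("MPO", "APOB"),
                        disease = "hypercholesterolemia",
                        score = c(0.9, 0.8))
  net <- assemble_network(calls, overall, votes, edges, gda = gda)
  mpo <- net$nodes[net$nodes$id == "MPO", ]
  expect_equal(mpo$provenance, "gda")
  dis <- net$nodes[net$nodes$kind == "disease", ]
  expect_equal(dis$id, "hypercholesterolemia")
  # query provenance wins over gda for queried genes
  expect_equal(net$nodes$provenance[net$nodes$id == "APOB"], "query")
})

test_that("assembly is deterministic and exports are byte-stable", {
  calls <- calls_fixture() |>
    dplyr::mutate(layer = c("PRO", "PRO", "PRO", "MIR", "MIR", "MIR"))
  overall <- tibble::tibble(molecule_id = calls$molecule_id,
                            overall_fc = c(2.1, -1.8, NA, -2.2, -2.0, 2.4))
  votes <- tibble::tibble(molecule_id = calls$molecule_id,
                          votes = c(7, 5, 2, 2, 2, 2), retained = TRUE)
  pooled <- load_edges(edges_fixture()) |> filter_ppi() |>
    inverse_regulation_filter(calls)
  net1 <- assemble_network(calls, overall, votes, pooled)
  net2 <- assemble_network(calls[sample(nrow(calls)), ], overall, votes,
                           pooled[sample(nrow(pooled)), ])
  expect_equal(net1$nodes, net2$nodes)
  expect_equal(net1$edges, net2$edges)
  dir <- withr::local_tempdir()
  g1 <- file.path(dir, "n1.graphml"); g2 <- file.path(dir, "n2.graphml")
  write_network_graphml(net1, g1); write_network_graphml(net2, g2)
  expect_identical(readLines(g1), readLines(g2))
  s1 <- file.path(dir, "n1.sif"); s2 <- file.path(dir, "n2.sif")
  write_network_sif(net1, s1); write_network_sif(net2, s2)
  expect_identical(readLines(s1), readLines(s2))
})

test_that("reaction nodes may only touch enzymes and compounds", {
  calls <- tibble::tibble(molecule_id = "GENE1", direction = "up",
                          winning_pct = 100, stratum_used = 2,
                          threshold = 60, layer = "PRO")
  overall <- tibble::tibble(molecule_id = "GENE1", overall_fc = 2)
  votes <- tibble::tibble(molecule_id = "GENE1", votes = 2, retained = TRUE)
  bad <- tibble::tibble(source = "RX1", target = "GENE1",
                        kind = "reaction_compound", confidence = NA_real_)
  # the reaction edge would tie a reaction to a gene/protein node
  expect_error(assemble_network(calls, overall, votes, bad),
               "enzyme and compound")
})
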