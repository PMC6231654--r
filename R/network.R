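EDGE_KINDS <- c("ppi", "mir_target_predicted", "mir_target_validated",
                "tf_target", "gene_enzyme", "enzyme_reaction",
                "reaction_compound", "gda")

NODE_KINDS <- c("mirna", "gene_protein", "enzyme", "reaction", "compound",
                "tf", "disease")

# Node kinds implied by each edge kind (source kind, target kind).
EDGE_ENDPOINT_KINDS <- list(
  ppi = c("gene_protein", "gene_protein"),
  mir_target_predicted = c("mirna", "gene_protein"),
  mir_target_validated = c("mirna", "gene_protein"),
  tf_target = c("tf", "gene_protein"),
  gene_enzyme = c("gene_protein", "enzyme"),
  enzyme_reaction = c("enzyme", "reaction"),
  reaction_compound = c("reaction", "compound"),
  gda = c("gene_protein", "disease")
)

#' Read an interaction edge-list file
#'
#' Accepts SIF (`source<TAB>relation<TAB>target[<TAB>confidence]`, no header)
#' or TSV (`source`, `target`, optional `confidence` columns, with header).
#' Protein-protein interaction (ppi) edges must carry a confidence score in
#' [0, 1]; a ppi file without a confidence column is rejected.
#'
#' @param path path to the file.
#' @param kind edge kind: one of ppi, mir_target_predicted,
#'   mir_target_validated, tf_target, gene_enzyme, enzyme_reaction,
#'   reaction_compound, gda.
#' @param format `"tsv"` or `"sif"`.
#' @return A tibble with `source`, `target`, `kind`, `confidence`.
#' @export
read_edge_file <- function(path, kind, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (!kind %in% EDGE_KINDS) {
    abort(paste0("Unknown edge kind '", kind, "'."))
  }
  if (format == "sif") {
    raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
    if (ncol(raw) < 3) abort(paste0(path, ": SIF needs >= 3 columns."))
    edges <- tibble::tibble(
      source = as.character(raw[[1]]),
      target = as.character(raw[[3]]),
      confidence = if (ncol(raw) >= 4) as.numeric(raw[[4]]) else NA_real_
    )
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE)
    if (!all(c("source", "target") %in% names(raw))) {
      abort(paste0(path, " needs `source` and `target` columns."))
    }
    edges <- tibble::tibble(
      source = as.character(raw$source),
      target = as.character(raw$target),
      confidence = if ("confidence" %in% names(raw)) {
        as.numeric(raw$confidence)
      } else NA_real_
    )
  }
  edges$kind <- kind
  if (kind == "ppi" && anyNA(edges$confidence)) {
    abort("ppi edges require a confidence score.")
  }
  if (any(!is.na(edges$confidence) &
          (edges$confidence < 0 | edges$confidence > 1))) {
    abort("Confidence scores must lie in [0, 1].")
  }
  edges[, c("source", "target", "kind", "confidence")]
}

#' Load and pool interaction edges
#'
#' Resolves edge endpoints through the synonym table (when given), drops
#' edges with unresolvable endpoints, and deduplicates edges keeping the
#' maximum confidence. Skipped edges are counted in the `load_report`
#' attribute, never silently lost.
#'
#' @param edges tibble of edges (`source`, `target`, `kind`, optional
#'   `confidence`), e.g. rows of [read_edge_file()] bound together.
#' @param clusters optional synonym table ([read_cluster_table()]); when
#'   supplied, endpoints are mapped to cluster ids and unresolvable
#'   endpoints cause the edge to be skipped.
#' @return The pooled edge tibble, with attribute `load_report` (tibble
#'   `n_input`, `n_skipped`, `n_deduplicated`).
#' @export
load_edges <- function(edges, clusters = NULL) {
  edges <- tibble::as_tibble(edges)
  if (!"confidence" %in% names(edges)) edges$confidence <- NA_real_
  bad_kind <- setdiff(unique(edges$kind), EDGE_KINDS)
  if (length(bad_kind) > 0) {
    abort(paste0("Unknown edge kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  n_input <- nrow(edges)
  n_skipped <- 0L
  if (!is.null(clusters)) {
    nm <- unique(c(edges$source, edges$target))
    res <- resolve_synonyms(nm, clusters)
    map <- setNames(res$resolved$cluster_id, res$resolved$name)
    ok <- edges$source %in% names(map) & edges$target %in% names(map)
    n_skipped <- sum(!ok)
    if (n_skipped > 0) {
      inform(sprintf("%d edge(s) with unresolvable endpoint(s) skipped.",
                     n_skipped))
    }
    edges <- edges[ok, ]
    edges$source <- unname(map[edges$source])
    edges$target <- unname(map[edges$target])
  }
  pooled <- edges |>
    dplyr::group_by(.data$source, .data$target, .data$kind) |>
    dplyr::summarise(
      confidence = if (all(is.na(.data$confidence))) NA_real_
                   else max(.data$confidence, na.rm = TRUE),
      .groups = "drop"
    )
  attr(pooled, "load_report") <- tibble::tibble(
    n_input = n_input, n_skipped = n_skipped,
    n_deduplicated = n_input - n_skipped - nrow(pooled)
  )
  pooled
}

#' Filter protein-protein interaction edges by confidence
#'
#' Retains ppi edges whose confidence reaches `min_confidence` (inclusive,
#' default 0.7); edges of any other kind pass through untouched. The filter
#' is idempotent.
#'
#' @param edges pooled edge tibble.
#' @param min_confidence minimum ppi confidence (default 0.7).
#' @return The filtered edge tibble.
#' @export
filter_ppi <- function(edges, min_confidence = 0.7) {
  edges |>
    dplyr::filter(.data$kind != "ppi" |
                    .data$confidence >= min_confidence)
}

#' Keep only inversely regulated miRNA-target edges
#'
#' MicroRNAs repress their targets, so a credible miRNA-target interaction in
#' the assembled model joins a down-regulated miRNA to an up-regulated target
#' or vice versa. Edges of kind `mir_target_predicted` or
#' `mir_target_validated` are retained iff both endpoints carry opposite
#' consensus directions in `{up, down}`; endpoints lacking a call or called
#' discordant drop the edge with a logged reason (attribute `drop_report`).
#' An optional magnitude floor restricts to miRNAs with |overall FC| at
#' least `min_magnitude`.
#'
#' @param edges pooled edge tibble.
#' @param calls consensus calls from [consensus_direction()].
#' @param overall optional output of [overall_fold_change()] used with
#'   `min_magnitude`.
#' @param min_magnitude optional minimum |overall fold-change| of the miRNA
#'   endpoint.
#' @return The filtered edge tibble with a `drop_report` attribute (tibble
#'   `source`, `target`, `reason`).
#' @export
inverse_regulation_filter <- function(edges, calls, overall = NULL,
                                      min_magnitude = NULL) {
  mir_kinds <- c("mir_target_predicted", "mir_target_validated")
  is_mir <- edges$kind %in% mir_kinds
  mir_edges <- edges[is_mir, ]
  dirs <- setNames(calls$direction, calls$molecule_id)
  src_dir <- dirs[mir_edges$source]
  tgt_dir <- dirs[mir_edges$target]
  reason <- rep(NA_character_, nrow(mir_edges))
  reason[is.na(src_dir) | is.na(tgt_dir)] <- "endpoint lacks consensus call"
  need <- is.na(reason)
  disc <- need & (src_dir == "discordant" | tgt_dir == "discordant")
  reason[disc] <- "endpoint discordant"
  need <- is.na(reason)
  same <- need & (src_dir == tgt_dir)
  reason[same] <- "same direction"
  if (!is.null(min_magnitude)) {
    if (is.null(overall)) {
      abort("`overall` is required when `min_magnitude` is set.")
    }
    mags <- setNames(abs(overall$overall_fc), overall$molecule_id)
    weak <- is.na(reason) &
      (is.na(mags[mir_edges$source]) |
         mags[mir_edges$source] < min_magnitude)
    reason[weak] <- "miRNA below magnitude floor"
  }
  keep <- is.na(reason)
  drop_report <- tibble::tibble(
    source = mir_edges$source[!keep],
    target = mir_edges$target[!keep],
    reason = reason[!keep]
  )
  out <- dplyr::bind_rows(edges[!is_mir, ], mir_edges[keep, ]) |>
    dplyr::arrange(.data$kind, .data$source, .data$target)
  attr(out, "drop_report") <- drop_report
  out
}

#' Assemble the heterogeneous molecular network
#'
#' Builds a typed multi-layer graph from the query molecules (with their
#' consensus calls, overall fold-changes and report counts), the pooled edge
#' evidence, and an optional gene-disease association table. Node kinds are
#' inferred from the edge kinds touching them (miRNA-target edges make their
#' source a `mirna` node, reaction-compound edges make their target a
#' `compound`, and so on); query molecules default to their layer's kind.
#' Nodes gain `provenance` `"query"`, `"inferred"` (brought in by an edge) or
#' `"gda"`; disease terms become `disease` nodes. Isolated inferred nodes are
#' pruned when `prune_isolated` is `TRUE`.
#'
#' @param calls consensus calls of the query molecules
#'   ([consensus_direction()]), optionally with a `layer` column.
#' @param overall overall fold-changes ([overall_fold_change()]).
#' @param votes vote counts ([vote_count()]), used for `report_count`.
#' @param edges pooled (and filtered) edge tibble.
#' @param gda optional tibble `gene`, `disease`, `score` of gene-disease
#'   associations; genes absent from the queries are added with provenance
#'   `"gda"`.
#' @param layers optional named vector molecule_id -> layer used to type
#'   query nodes (MIR -> mirna, MET -> compound, otherwise gene_protein).
#' @param prune_isolated drop inferred nodes of degree 0 (default `TRUE`).
#' @return An object of class `hetero_network`: list with `nodes`, `edges`
#'   tibbles and the `igraph` graph.
#' @export
assemble_network <- function(calls, overall, votes, edges, gda = NULL,
                             layers = NULL, prune_isolated = TRUE) {
  edges <- tibble::as_tibble(edges)
  if (!is.null(gda)) {
    stopifnot(all(c("gene", "disease") %in% names(gda)))
    gda_edges <- tibble::tibble(
      source = as.character(gda$gene),
      target = as.character(gda$disease),
      kind = "gda",
      confidence = if ("score" %in% names(gda)) as.numeric(gda$score)
                   else NA_real_
    )
    edges <- dplyr::bind_rows(edges, gda_edges)
  }

  node_kind <- character()
  # queries first: layer decides the kind
  query_ids <- unique(calls$molecule_id)
  if (is.null(layers) && "layer" %in% names(calls)) {
    layers <- setNames(calls$layer, calls$molecule_id)
  }
  query_kind <- if (is.null(layers)) {
    rep("gene_protein", length(query_ids))
  } else {
    unname(c(MIR = "mirna", GENE = "gene_protein", PRO = "gene_protein",
             MET = "compound")[layers[query_ids]])
  }
  query_kind[is.na(query_kind)] <- "gene_protein"
  node_kind[query_ids] <- query_kind
  # then edge-implied kinds for remaining endpoints
  if (nrow(edges) > 0) {
    for (k in unique(edges$kind)) {
      ek <- EDGE_ENDPOINT_KINDS[[k]]
      sub <- edges[edges$kind == k, ]
      for (ids_kind in list(list(sub$source, ek[1]),
                            list(sub$target, ek[2]))) {
        ids <- ids_kind[[1]]
        missing_ids <- ids[!ids %in% names(node_kind)]
        if (length(missing_ids) > 0) {
          node_kind[missing_ids] <- ids_kind[[2]]
        }
      }
    }
  }

  nodes <- tibble::tibble(
    id = names(node_kind),
    kind = unname(node_kind),
    provenance = ifelse(names(node_kind) %in% query_ids, "query", "inferred")
  )
  if (!is.null(gda)) {
    nodes$provenance[nodes$id %in% as.character(gda$gene) &
                       nodes$provenance != "query"] <- "gda"
    nodes$kind[nodes$id %in% as.character(gda$disease)] <- "disease"
  }
  nodes <- nodes |>
    dplyr::left_join(calls |>
                       dplyr::select("molecule_id", "direction"),
                     by = c(id = "molecule_id")) |>
    dplyr::left_join(overall |>
                       dplyr::select("molecule_id", "overall_fc"),
                     by = c(id = "molecule_id")) |>
    dplyr::left_join(votes |>
                       dplyr::select("molecule_id", report_count = "votes"),
                     by = c(id = "molecule_id"))

  # drop edges whose endpoints are unknown (should not happen) and validate
  edges <- edges |>
    dplyr::filter(.data$source %in% nodes$id, .data$target %in% nodes$id)
  validate_reaction_edges(edges, nodes)

  if (prune_isolated) {
    touched <- unique(c(edges$source, edges$target))
    nodes <- nodes |>
      dplyr::filter(.data$provenance == "query" | .data$id %in% touched)
    edges <- edges |>
      dplyr::filter(.data$source %in% nodes$id, .data$target %in% nodes$id)
  }

  nodes <- dplyr::arrange(nodes, .data$id)
  edges <- dplyr::arrange(edges, .data$kind, .data$source, .data$target)
  g <- igraph::graph_from_data_frame(
    edges |> dplyr::rename(from = "source", to = "target"),
    directed = FALSE,
    vertices = nodes
  )
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "hetero_network")
}

validate_reaction_edges <- function(edges, nodes) {
  kind_of <- setNames(nodes$kind, nodes$id)
  rx <- edges[kind_of[edges$source] == "reaction" |
                kind_of[edges$target] == "reaction", ]
  if (nrow(rx) == 0) return(invisible(TRUE))
  other <- ifelse(kind_of[rx$source] == "reaction",
                  kind_of[rx$target], kind_of[rx$source])
  if (any(!other %in% c("enzyme", "compound"))) {
    abort("Reaction nodes may connect only to enzyme and compound nodes.")
  }
  invisible(TRUE)
}

#' @method print hetero_network
#' @export
print.hetero_network <- function(x, ...) {
  cat("<hetero_network>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  tab <- table(x$nodes$kind)
  cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @rdname assemble_network
#' @param x a `hetero_network` (for the tidier).
#' @param ... unused.
#' @method tidy hetero_network
#' @export
tidy.hetero_network <- function(x, ...) {
  x$nodes
}

#' @rdname assemble_network
#' @method glance hetero_network
#' @export
glance.hetero_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_query = sum(x$nodes$provenance == "query"),
    n_inferred = sum(x$nodes$provenance == "inferred"),
    n_gda = sum(x$nodes$provenance == "gda")
  )
}

#' Export a heterogeneous network
#'
#' Writes the network as GraphML (via igraph) or SIF plus a node-attribute
#' TSV. Nodes and edges are sorted, so repeated exports of the same network
#' are byte-identical.
#'
#' @param network a `hetero_network`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(network, path) {
  g <- network$graph
  # graphml cannot carry NA logicals/characters; normalise attributes
  for (at in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, at)
    if (is.character(v)) v[is.na(v)] <- ""
    if (is.numeric(v)) v[is.na(v)] <- NaN
    g <- igraph::set_vertex_attr(g, at, value = v)
  }
  for (at in igraph::edge_attr_names(g)) {
    v <- igraph::edge_attr(g, at)
    if (is.character(v)) v[is.na(v)] <- ""
    if (is.numeric(v)) v[is.na(v)] <- NaN
    g <- igraph::set_edge_attr(g, at, value = v)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_sif <- function(network, path) {
  sif <- network$edges |>
    dplyr::transmute(.data$source, .data$kind, .data$target)
  readr::write_tsv(sif, path, col_names = FALSE)
  node_path <- paste0(path, ".nodes.tsv")
  readr::write_tsv(network$nodes, node_path)
  invisible(path)
}
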