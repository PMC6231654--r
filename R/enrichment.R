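#' Read a gene-set collection in GMT format
#'
#' GMT files carry one set per line: set id, description, then tab-separated
#' members. The universe defaults to the union of all members of the loaded
#' collection; an explicit universe may be supplied instead.
#'
#' @param path path to the GMT file.
#' @param universe optional character vector of identifiers forming the
#'   background; defaults to the union of all set members.
#' @return An object of class `gene_set_collection`: list with `sets`
#'   (tibble `set_id`, `name`, `members` list-column) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", which(bad)[1]))
  }
  sets <- tibble::tibble(
    set_id = purrr::map_chr(parts, 1),
    name = purrr::map_chr(parts, 2),
    members = purrr::map(parts, ~ unique(.x[-(1:2)]))
  )
  gene_set_collection(sets, universe)
}

#' Build a gene-set collection from a tibble of sets
#'
#' @param sets tibble with `set_id`, `name` and a `members` list-column.
#' @param universe optional background identifiers; defaults to the union of
#'   all members. Every set member must belong to the universe; sets must be
#'   non-empty.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(all(c("set_id", "members") %in% names(sets)))
  if (!"name" %in% names(sets)) sets$name <- sets$set_id
  if (any(lengths(sets$members) == 0)) abort("Sets must be non-empty.")
  all_members <- unique(unlist(sets$members))
  if (is.null(universe)) {
    universe <- all_members
  } else {
    universe <- unique(universe)
    if (length(universe) == 0) abort("Universe must be non-empty.")
    outside <- setdiff(all_members, universe)
    if (length(outside) > 0) {
      abort("Every set member must belong to the universe.")
    }
  }
  structure(list(sets = tibble::as_tibble(sets), universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection>", nrow(x$sets), "sets, universe of",
      length(x$universe), "identifiers\n")
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For each set, tests whether the query list intersects it more than
#' expected when drawing |query| identifiers without replacement from the
#' universe: the p-value is the upper tail P(X >= hits) of the hypergeometric
#' law with population |universe|, successes |set| and draws |query|.
#' Query members outside the universe are dropped with a message.
#'
#' @param query character vector of query identifiers.
#' @param collection a [gene_set_collection()].
#' @param adjust `"none"` (default; the raw p-values are reported) or
#'   `"benjamini_hochberg"` for step-up FDR adjustment.
#' @return A tibble sorted by ascending p-value with columns `set_id`,
#'   `name`, `total` (set size), `hits`, `p_value`, `topology` (`NA`, filled
#'   by [degree_centrality_topology()] when a pathway graph is available),
#'   `matched` (list-column), `adjusted_p`.
#' @examples
#' gsc <- gene_set_collection(
#'   tibble::tibble(set_id = "s1", name = "s1",
#'                  members = list(c("a", "b", "c"))),
#'   universe = letters[1:10]
#' )
#' hypergeometric_ora(c("a", "b", "d"), gsc)
#' @export
hypergeometric_ora <- function(query, collection,
                               adjust = c("none", "benjamini_hochberg")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- collection$universe
  if (length(universe) == 0) abort("Universe is empty.")
  query <- unique(query)
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0) {
    inform(sprintf("%d query identifier(s) outside the universe dropped.",
                   length(dropped)))
  }
  query <- intersect(query, universe)
  if (length(query) == 0) {
    warn("Empty query after universe intersection; returning no results.")
    return(tibble::tibble(
      set_id = character(), name = character(), total = integer(),
      hits = integer(), p_value = numeric(), topology = numeric(),
      matched = list(), adjusted_p = numeric()
    ))
  }
  res <- collection$sets |>
    dplyr::mutate(
      total = lengths(.data$members),
      matched = purrr::map(.data$members, ~ intersect(query, .x)),
      hits = lengths(.data$matched),
      p_value = stats::phyper(.data$hits - 1, .data$total,
                              length(universe) - .data$total,
                              length(query), lower.tail = FALSE),
      topology = NA_real_
    ) |>
    dplyr::select("set_id", "name", "total", "hits", "p_value",
                  "topology", "matched") |>
    dplyr::arrange(.data$p_value, .data$set_id)
  res$adjusted_p <- adjust_pvalues(res$p_value, adjust)
  res
}

#' Adjust a vector of p-values
#'
#' @param p numeric vector of p-values.
#' @param method `"none"` (copy through) or `"benjamini_hochberg"`
#'   (step-up FDR).
#' @return Adjusted p-values, same length as `p`.
#' @export
adjust_pvalues <- function(p, method = c("none", "benjamini_hochberg")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  switch(method,
    none = p,
    benjamini_hochberg = stats::p.adjust(p, method = "BH")
  )
}

#' Read a pathway graph from a SIF or two-column edge list
#'
#' SIF lines are `source<TAB>relation<TAB>target`; two-column TSVs are
#' `source<TAB>target` with a header. Self-loops are rejected.
#'
#' @param path path to the file.
#' @param format `"sif"` or `"tsv"`.
#' @param pathway_id identifier attached to the graph.
#' @return A list of class `pathway_graph` with `pathway_id`, `nodes` and an
#'   `edges` tibble (`source`, `target`).
#' @export
read_pathway_graph <- function(path, format = c("sif", "tsv"),
                               pathway_id = basename(path)) {
  format <- match.arg(format)
  if (format == "sif") {
    raw <- readr::read_tsv(path, col_names = c("source", "relation", "target"),
                           show_col_types = FALSE)
    edges <- raw[, c("source", "target")]
  } else {
    edges <- readr::read_tsv(path, show_col_types = FALSE)[, 1:2]
    names(edges) <- c("source", "target")
  }
  pathway_graph(edges, pathway_id)
}

#' Build a pathway graph from an edge tibble
#'
#' @param edges tibble with `source` and `target` columns (undirected).
#' @param pathway_id identifier for the pathway.
#' @param nodes optional node identifiers; defaults to all edge endpoints.
#' @return A `pathway_graph` object.
#' @export
pathway_graph <- function(edges, pathway_id = "pathway", nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (any(edges$source == edges$target)) {
    abort("Pathway graphs may not contain self-loops.")
  }
  endpoint <- unique(c(edges$source, edges$target))
  if (is.null(nodes)) {
    nodes <- endpoint
  } else if (length(setdiff(endpoint, nodes)) > 0) {
    abort("Edges reference nodes missing from `nodes`.")
  }
  structure(list(pathway_id = pathway_id, nodes = nodes,
                 edges = dplyr::distinct(edges)),
            class = "pathway_graph")
}

#' Degree-centrality pathway topology score
#'
#' The topology score of a matched molecule set within a pathway is the sum
#' over matched nodes of their degree centrality deg(v)/(n - 1), where n is
#' the number of pathway nodes. The score is additive over matched nodes and
#' can exceed 1 when several matched nodes are well connected. Matched
#' identifiers absent from the pathway are ignored with a warning; a pathway
#' with fewer than 2 nodes has undefined topology and scores 0.
#'
#' @param graph a [pathway_graph()].
#' @param matched character vector of matched molecule identifiers.
#' @return A single non-negative score.
#' @examples
#' g <- pathway_graph(tibble::tibble(source = c("A", "B"),
#'                                   target = c("B", "C")))
#' degree_centrality_topology(g, "B") # middle of a 3-path: 1.0
#' @export
degree_centrality_topology <- function(graph, matched) {
  stopifnot(inherits(graph, "pathway_graph"))
  n <- length(graph$nodes)
  if (n < 2) {
    warn("Pathway has fewer than 2 nodes; topology undefined, scoring 0.")
    return(0)
  }
  outside <- setdiff(matched, graph$nodes)
  if (length(outside) > 0) {
    warn(sprintf("%d matched identifier(s) not in the pathway ignored.",
                 length(outside)))
  }
  matched <- intersect(matched, graph$nodes)
  if (length(matched) == 0) return(0)
  deg_tab <- table(c(graph$edges$source, graph$edges$target))
  deg <- as.numeric(deg_tab[matched])
  deg[is.na(deg)] <- 0
  sum(deg / (n - 1))
}
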