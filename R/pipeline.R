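#' Pipeline configuration
#'
#' Collects every tunable of the staged pipeline into one serialisable
#' object. A configuration can be built in code or loaded from YAML with
#' [read_pipeline_config()]; the resolved configuration of each run is
#' echoed into the output directory so runs are self-describing. All
#' randomness flows from the single top-level `seed`.
#'
#' @param input_dir directory holding the input TSVs (an expression table
#'   `expression_records.tsv` and metadata `study_metadata.tsv`; the
#'   `simulate` stage writes them).
#' @param output_dir directory for stage outputs (created if needed).
#' @param scheme `"case_study"` or `"curation"`.
#' @param fc_dialect fold-change dialect of the expression table.
#' @param min_votes minimum votes for retention.
#' @param consensus_threshold prevalence threshold in percent.
#' @param strata fold-change strata.
#' @param min_reports minimum studies per molecule for the DE matrix.
#' @param ppi_min_confidence minimum ppi confidence.
#' @param seed top-level integer seed.
#' @param gmt optional path to a GMT collection (enrich stage).
#' @param edge_files optional named list kind -> path of edge files
#'   (network stage).
#' @param simulate optional [corpus_config()] overrides as a named list
#'   (simulate stage).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            scheme = "case_study",
                            fc_dialect = "signed",
                            min_votes = 2,
                            consensus_threshold = 60,
                            strata = c(1.3, 1.5, 2.0),
                            min_reports = 3,
                            ppi_min_confidence = 0.7,
                            seed = 1L,
                            gmt = NULL,
                            edge_files = NULL,
                            simulate = NULL) {
  if (!scheme %in% c("case_study", "curation")) {
    abort("`scheme` must be 'case_study' or 'curation'.")
  }
  if (!fc_dialect %in% c("signed", "ratio")) {
    abort("`fc_dialect` must be 'signed' or 'ratio'.")
  }
  if (min_votes < 1) abort("`min_votes` must be >= 1.")
  if (consensus_threshold <= 50) {
    abort("`consensus_threshold` must be > 50.")
  }
  structure(
    list(input_dir = input_dir, output_dir = output_dir, scheme = scheme,
         fc_dialect = fc_dialect, min_votes = min_votes,
         consensus_threshold = consensus_threshold, strata = strata,
         min_reports = min_reports,
         ppi_min_confidence = ppi_min_confidence, seed = as.integer(seed),
         gmt = gmt, edge_files = edge_files, simulate = simulate),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path path of a YAML file with `pipeline_config` fields.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad) > 0) {
    abort(paste0("Unknown config field(s): ", paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run a pipeline stage
#'
#' Orchestrates the staged pipeline on disk: `simulate` writes a seeded
#' synthetic corpus into `input_dir`; `harmonize` canonicalizes and collapses
#' the expression table; `meta` runs the vote-counting meta-analysis;
#' `enrich` runs over-representation of the retained molecules against the
#' configured GMT; `dimred` builds the log2 fold-change matrix and runs PCA
#' (and NMDS when enough studies are present); `network` pools the configured
#' edge files, applies the confidence and inverse-regulation filters and
#' assembles the heterogeneous network; `all` chains every stage. Each stage
#' writes its outputs plus a `manifest_<stage>.json` (input file hashes,
#' seed, package version, resolved config echo), so reruns on identical
#' inputs are reproducible and identical.
#'
#' @param stage one of `"simulate"`, `"harmonize"`, `"meta"`, `"enrich"`,
#'   `"dimred"`, `"network"`, `"all"`.
#' @param config a [pipeline_config()].
#' @return Invisibly, a named list of artifact paths written by the stage(s).
#' @export
run_stage <- function(stage = c("all", "simulate", "harmonize", "meta",
                                "enrich", "dimred", "network"),
                      config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  stages <- if (stage == "all") {
    c("simulate", "harmonize", "meta", "enrich", "dimred", "network")
  } else {
    stage
  }
  out <- list()
  for (st in stages) {
    fn <- switch(st,
      simulate = stage_simulate, harmonize = stage_harmonize,
      meta = stage_meta, enrich = stage_enrich,
      dimred = stage_dimred, network = stage_network
    )
    out[[st]] <- fn(config)
    write_manifest(st, config, out[[st]])
  }
  invisible(out)
}

path_in <- function(config, name) file.path(config$input_dir, name)
path_out <- function(config, name) file.path(config$output_dir, name)

require_input <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Missing input file: ", path))
  }
  path
}

write_manifest <- function(stage, config, artifacts) {
  artifacts <- unlist(artifacts)
  hashes <- vapply(artifacts, function(p) {
    unname(tools::md5sum(p))
  }, character(1))
  manifest <- list(
    stage = stage,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("omicsvote")),
    config = unclass(config),
    artifacts = as.list(setNames(hashes, basename(artifacts)))
  )
  jsonlite::write_json(manifest,
                       path_out(config, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

stage_simulate <- function(config) {
  args <- config$simulate %||% list()
  args$seed <- config$seed
  cc <- do.call(corpus_config, args)
  corpus <- generate_corpus(cc)
  write_corpus(corpus, config$input_dir)
}

stage_harmonize <- function(config) {
  rec <- read_expression_table(
    require_input(path_in(config, "expression_records.tsv")),
    fc_dialect = config$fc_dialect
  )
  collapsed <- collapse_records(rec)
  p <- path_out(config, "harmonized_records.tsv")
  readr::write_tsv(collapsed, p)
  c(harmonized = p)
}

read_harmonized <- function(config) {
  validate_records(readr::read_tsv(
    require_input(path_out(config, "harmonized_records.tsv")),
    show_col_types = FALSE
  ))
}

stage_meta <- function(config) {
  collapsed <- read_harmonized(config)
  scheme <- threshold_scheme(config$scheme, strata = config$strata)
  fit <- meta_analyse(collapsed, scheme, config$min_votes,
                      config$consensus_threshold)
  inform(sprintf(
    "Consensus read at the per-layer DE cutoff strata (%s); p < %g; |FC| cutoffs %s.",
    paste(scheme$strata, collapse = "/"), scheme$p_cutoff,
    paste(sprintf("%s=%.1f", names(scheme$de_fc_cutoff),
                  scheme$de_fc_cutoff), collapse = " ")
  ))
  paths <- c(
    frequency = path_out(config, "frequency_table.tsv"),
    calls = path_out(config, "consensus_calls.tsv"),
    summary = path_out(config, "meta_summary.tsv")
  )
  readr::write_tsv(fit$freq, paths[["frequency"]])
  readr::write_tsv(fit$calls, paths[["calls"]])
  readr::write_tsv(fit$summary, paths[["summary"]])
  paths
}

stage_enrich <- function(config) {
  summary_path <- require_input(path_out(config, "meta_summary.tsv"))
  summary <- readr::read_tsv(summary_path, show_col_types = FALSE)
  if (is.null(config$gmt)) {
    inform("No GMT configured; enrich stage writes an empty result.")
    res <- hypergeometric_empty()
  } else {
    gsc <- read_gmt(require_input(config$gmt))
    query <- summary$molecule_id
    res <- suppressWarnings(hypergeometric_ora(query, gsc))
  }
  p <- path_out(config, "enrichment.tsv")
  readr::write_tsv(res |>
                     dplyr::mutate(matched = purrr::map_chr(
                       .data$matched, paste, collapse = "|")), p)
  c(enrichment = p)
}

hypergeometric_empty <- function() {
  tibble::tibble(
    set_id = character(), name = character(), total = integer(),
    hits = integer(), p_value = numeric(), topology = numeric(),
    matched = list(), adjusted_p = numeric()
  )
}

stage_dimred <- function(config) {
  collapsed <- read_harmonized(config)
  dm <- build_de_matrix(collapsed, config$min_reports)
  paths <- c(matrix = path_out(config, "de_matrix.tsv"))
  write_de_matrix(dm, paths[["matrix"]])
  pca <- run_pca(dm)
  paths[["pca_scores"]] <- path_out(config, "pca_scores.tsv")
  readr::write_tsv(tibble::as_tibble(pca$scores, rownames = "study_id"),
                   paths[["pca_scores"]])
  paths[["pca_variance"]] <- path_out(config, "pca_variance.tsv")
  readr::write_tsv(tibble::tibble(
    component = seq_along(pca$variance_fraction),
    variance_fraction = pca$variance_fraction
  ), paths[["pca_variance"]])
  if (ncol(dm$matrix) >= 3) {
    nmds <- run_nmds(dm, dims = 2, seed = config$seed)
    paths[["nmds"]] <- path_out(config, "nmds_coordinates.tsv")
    readr::write_tsv(
      tibble::as_tibble(nmds$points, rownames = "study_id") |>
        dplyr::mutate(stress = nmds$stress),
      paths[["nmds"]]
    )
  }
  paths
}

stage_network <- function(config) {
  collapsed <- read_harmonized(config)
  calls <- readr::read_tsv(
    require_input(path_out(config, "consensus_calls.tsv")),
    show_col_types = FALSE
  )
  summary <- readr::read_tsv(
    require_input(path_out(config, "meta_summary.tsv")),
    show_col_types = FALSE
  )
  votes <- summary |> dplyr::select("molecule_id", "votes") |>
    dplyr::mutate(retained = TRUE)
  overall <- summary |> dplyr::select("molecule_id", "overall_fc")
  layer_map <- collapsed |>
    dplyr::distinct(.data$molecule_id, .data$layer)
  layers <- setNames(layer_map$layer, layer_map$molecule_id)

  edges <- if (is.null(config$edge_files)) {
    tibble::tibble(source = character(), target = character(),
                   kind = character(), confidence = numeric())
  } else {
    purrr::imap(config$edge_files, function(p, kind) {
      read_edge_file(require_input(p), kind)
    }) |> purrr::list_rbind()
  }
  pooled <- load_edges(edges) |>
    filter_ppi(config$ppi_min_confidence) |>
    inverse_regulation_filter(calls)
  net <- assemble_network(calls, overall, votes, pooled, layers = layers)
  paths <- c(
    graphml = path_out(config, "network.graphml"),
    sif = path_out(config, "network.sif")
  )
  write_network_graphml(net, paths[["graphml"]])
  write_network_sif(net, paths[["sif"]])
  paths
}
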