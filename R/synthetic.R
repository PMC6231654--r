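#' Configuration for the synthetic multi-omics corpus generator
#'
#' The generator emulates the statistical shape of a curated multi-study
#' differential-expression corpus: a handful of studies per omics layer
#' (defaults mirror the coronary-artery-disease subset: 2 miRNA, 9 protein,
#' 10 metabolite studies), heterogeneous molecule coverage with heavy
#' missingness, signed fold-changes with configurable direction concordance,
#' and p-values drawn from a null/alternative mixture.
#'
#' Planted differentially expressed molecules draw |log2 FC| from a Normal
#' truncated to positive values (default mean 2, sd 0.75, i.e. fold-changes
#' centred on 4x — typical of reported DE calls, with microRNAs known to show
#' large fold-changes) and p-values from Beta(`alt_p_beta_shape`, 1) rescaled
#' below 0.05, so planted molecules always pass the p-gate. Null molecules
#' draw |log2 FC| from a half-Normal near zero (sd `null_fc_log2_sd`) and
#' p-values from Uniform(0, 1). Each (study, molecule) pair is observed
#' independently with probability `detection_prob`.
#'
#' @param studies_per_layer named integer vector of study counts per layer.
#' @param molecules_per_layer named integer vector of molecule counts per
#'   layer.
#' @param planted_de_fraction fraction of molecules planted as DE, in [0, 1].
#' @param direction_concordance probability a planted report shows the true
#'   direction, in [0.5, 1].
#' @param fc_magnitude_log2_mean mean of the planted |log2 FC| Normal.
#' @param fc_magnitude_log2_sd sd of the planted |log2 FC| Normal, > 0.
#' @param null_fc_log2_sd sd of the null half-Normal |log2 FC|, > 0.
#' @param alt_p_beta_shape shape of the Beta(shape, 1) alternative p-value
#'   law, > 0.
#' @param detection_prob probability a molecule is observed in a study,
#'   in (0, 1].
#' @param seed integer seed; identical config + seed reproduce an identical
#'   corpus.
#' @return An object of class `corpus_config`.
#' @export
corpus_config <- function(studies_per_layer = c(MIR = 2, GENE = 0,
                                                PRO = 9, MET = 10),
                          molecules_per_layer = c(MIR = 50, GENE = 0,
                                                  PRO = 50, MET = 50),
                          planted_de_fraction = 0.3,
                          direction_concordance = 0.8,
                          fc_magnitude_log2_mean = 2.0,
                          fc_magnitude_log2_sd = 0.75,
                          null_fc_log2_sd = 0.15,
                          alt_p_beta_shape = 0.5,
                          detection_prob = 0.5,
                          seed = 1L) {
  check_layers(names(studies_per_layer))
  check_layers(names(molecules_per_layer))
  if (planted_de_fraction < 0 || planted_de_fraction > 1) {
    abort("`planted_de_fraction` must lie in [0, 1].")
  }
  if (direction_concordance < 0.5 || direction_concordance > 1) {
    abort("`direction_concordance` must lie in [0.5, 1].")
  }
  if (fc_magnitude_log2_sd <= 0 || null_fc_log2_sd <= 0) {
    abort("Fold-change log2 sds must be > 0.")
  }
  if (alt_p_beta_shape <= 0) abort("`alt_p_beta_shape` must be > 0.")
  if (detection_prob <= 0 || detection_prob > 1) {
    abort("`detection_prob` must lie in (0, 1].")
  }
  structure(
    list(studies_per_layer = studies_per_layer,
         molecules_per_layer = molecules_per_layer,
         planted_de_fraction = planted_de_fraction,
         direction_concordance = direction_concordance,
         fc_magnitude_log2_mean = fc_magnitude_log2_mean,
         fc_magnitude_log2_sd = fc_magnitude_log2_sd,
         null_fc_log2_sd = null_fc_log2_sd,
         alt_p_beta_shape = alt_p_beta_shape,
         detection_prob = detection_prob,
         seed = as.integer(seed)),
    class = "corpus_config"
  )
}

#' Generate a synthetic multi-study multi-omics corpus
#'
#' Draws a seeded corpus under a [corpus_config()]: per-study canonical
#' expression records, study metadata, and the planted ground truth for
#' parameter-recovery benchmarks.
#'
#' @param config a [corpus_config()].
#' @return A list with `records` (canonical expression records), `metadata`
#'   (study metadata tibble) and `truth` (tibble `molecule_id`, `layer`,
#'   `is_de`, `direction`; direction `NA` for null molecules).
#' @examples
#' corpus <- generate_corpus(corpus_config(seed = 7))
#' dplyr::count(corpus$records, layer)
#' @export
generate_corpus <- function(config = corpus_config()) {
  stopifnot(inherits(config, "corpus_config"))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config$seed)
    code
  }
  withr_seed(generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  layers <- names(config$studies_per_layer)
  layers <- layers[config$studies_per_layer > 0]

  compartments <- c(MIR = "plasma", GENE = "blood", PRO = "plasma",
                    MET = "plasma")
  methods <- c(MIR = "miRNA-array", GENE = "gene-array",
               PRO = "LC-MS/MS", MET = "LC-QTOF-MS")

  metadata <- purrr::map(layers, function(ly) {
    n <- config$studies_per_layer[[ly]]
    tibble::tibble(
      study_id = sprintf("SIM_%s_%02d", ly, seq_len(n)),
      layer = ly,
      compartment = compartments[[ly]],
      n_total = sample(10:500, n, replace = TRUE),
      case_label = "case",
      control_label = "control",
      detection_method = methods[[ly]]
    )
  }) |> purrr::list_rbind()

  truth <- purrr::map(layers, function(ly) {
    m <- config$molecules_per_layer[[ly]]
    if (m == 0) return(NULL)
    is_de <- runif(m) < config$planted_de_fraction
    tibble::tibble(
      molecule_id = sprintf("%s_mol_%03d", ly, seq_len(m)),
      layer = ly,
      is_de = is_de,
      direction = ifelse(is_de, sample(c("up", "down"), m, replace = TRUE),
                         NA_character_)
    )
  }) |> purrr::list_rbind()

  records <- purrr::map(seq_len(nrow(metadata)), function(i) {
    st <- metadata[i, ]
    mols <- truth[truth$layer == st$layer, ]
    if (nrow(mols) == 0) return(NULL)
    seen <- runif(nrow(mols)) < config$detection_prob
    mols <- mols[seen, ]
    if (nrow(mols) == 0) return(NULL)
    n <- nrow(mols)

    l2 <- numeric(n)
    p <- numeric(n)
    dir_sign <- numeric(n)

    de <- mols$is_de
    n_de <- sum(de)
    if (n_de > 0) {
      mag <- rnorm(n_de, config$fc_magnitude_log2_mean,
                   config$fc_magnitude_log2_sd)
      while (any(mag <= 0)) {             # truncate to positive magnitudes
        mag[mag <= 0] <- rnorm(sum(mag <= 0), config$fc_magnitude_log2_mean,
                               config$fc_magnitude_log2_sd)
      }
      l2[de] <- mag
      concord <- runif(n_de) < config$direction_concordance
      true_sign <- ifelse(mols$direction[de] == "up", 1, -1)
      dir_sign[de] <- ifelse(concord, true_sign, -true_sign)
      p[de] <- 0.05 * rbeta(n_de, config$alt_p_beta_shape, 1)
    }
    if (n_de < n) {
      l2[!de] <- abs(rnorm(n - n_de, 0, config$null_fc_log2_sd))
      dir_sign[!de] <- sample(c(-1, 1), n - n_de, replace = TRUE)
      p[!de] <- runif(n - n_de)
    }
    p <- pmin(pmax(p, .Machine$double.xmin), 1)

    signed_l2 <- dir_sign * l2
    fc <- log2_to_signed_fc(signed_l2)
    tibble::tibble(
      study_id = st$study_id,
      molecule_id = mols$molecule_id,
      layer = st$layer,
      fc = fc,
      magnitude = abs(fc),
      direction = ifelse(abs(fc) == 1, "none",
                         ifelse(fc > 0, "up", "down")),
      p_value = p,
      compartment = st$compartment,
      species = "Homo sapiens"
    )
  }) |> purrr::list_rbind()

  list(records = validate_records(records), metadata = metadata,
       truth = truth)
}

#' Write a synthetic corpus to TSV files
#'
#' Serialises a generated corpus into the package's TSV dialects: an
#' expression table (signed fold-change dialect), a study metadata table and
#' the planted-truth table.
#'
#' @param corpus output of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (named character vector).
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    records = file.path(dir, "expression_records.tsv"),
    metadata = file.path(dir, "study_metadata.tsv"),
    truth = file.path(dir, "planted_truth.tsv")
  )
  rec <- corpus$records |>
    dplyr::select("study_id", molecule = "molecule_id", "layer", "fc",
                  "p_value", "compartment", "species")
  readr::write_tsv(rec, paths[["records"]])
  meta <- corpus$metadata |>
    dplyr::select("study_id", "layer", "compartment", "n_total",
                  "case_label", "control_label", "detection_method")
  readr::write_tsv(meta, paths[["metadata"]])
  readr::write_tsv(corpus$truth, paths[["truth"]])
  invisible(paths)
}
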