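#' Configuration of an end-to-end run
#'
#' Bundles everything a run needs; a saved config (plus the seed it
#' contains) fully reproduces the run's outputs.
#'
#' @param trees Input path (directory, files or multi-record JSON) or an
#'   in-memory cohort tibble.
#' @param format Tree file format for paths.
#' @param config A [vocab_config()].
#' @param params A [train_params()].
#' @param threshold Clustering cutoff (default 0.4).
#' @param n_anchors Anchor documents injected for training.
#' @param seed Master seed (overrides `params$seed`).
#' @param out Output directory, or `NULL` to skip writing.
#' @return A `run_config` list.
#' @export
run_config <- function(trees, format = "json", config = vocab_config(),
                       params = train_params(), threshold = 0.4,
                       n_anchors = 1L, seed = 1L, out = NULL) {
  structure(list(trees = trees, format = format, config = config,
                 params = params, threshold = threshold,
                 n_anchors = as.integer(n_anchors), seed = as.integer(seed),
                 out = out),
            class = "run_config")
}

#' Run the full embedding-and-clustering pipeline
#'
#' Executes parse -> vocabulary -> embedding -> clustering -> reports. When
#' `cfg$out` is set, writes the output bundle: `embeddings.tsv`,
#' `documents_embeddings.tsv`, `trace.csv`, `distances.csv`,
#' `clusters.tsv`, `dominant_words.tsv`, `vocabulary.tsv` and the resolved
#' `config.json` (including the seed), so a bundle is self-describing.
#' Duplicate and anchor documents never appear in the user-facing matrices.
#'
#' @param cfg A [run_config()].
#' @return A list: `cohort`, `documents`, `corpus`, `model`, `dist`,
#'   `clusters`, `dominant`, `convergence` (invisible when writing).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  cohort <- if (is.data.frame(cfg$trees)) cfg$trees else
    read_cohort(cfg$trees, cfg$format)
  ids <- unique(cohort$tree_id)

  documents <- build_corpus(cohort, cfg$config)
  corpus <- prepare_training_corpus(documents, tree_ids = ids,
                                    n_anchors = cfg$n_anchors, seed = cfg$seed)
  params <- cfg$params
  params$seed <- cfg$seed
  model <- train_embeddings(corpus, params)
  cut <- suppressWarnings(convergence_cutoff(model$trace))

  dist <- cosine_distance_matrix(model)
  clusters <- hierarchical_clusters(dist, threshold = cfg$threshold)
  dominant <- dominant_words(clusters, documents)

  bundle <- list(cohort = cohort, documents = documents, corpus = corpus,
                 model = model, dist = dist, clusters = clusters,
                 dominant = dominant, convergence = cut)
  if (!is.null(cfg$out)) {
    write_bundle(bundle, cfg)
    return(invisible(bundle))
  }
  bundle
}

write_bundle <- function(bundle, cfg) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  write_embeddings(bundle$model, cfg$out)
  write_distance_csv(bundle$dist, file.path(cfg$out, "distances.csv"))
  readr::write_tsv(bundle$clusters$assignments,
                   file.path(cfg$out, "clusters.tsv"))
  readr::write_tsv(bundle$dominant, file.path(cfg$out, "dominant_words.tsv"))
  dump_vocabulary(bundle$documents, file.path(cfg$out, "vocabulary.tsv"))
  resolved <- list(
    trees = if (is.data.frame(cfg$trees)) "(in-memory cohort)" else cfg$trees,
    format = cfg$format,
    vocab_config = unclass(cfg$config),
    train_params = utils::modifyList(unclass(bundle$model$params), list()),
    threshold = cfg$threshold,
    n_anchors = cfg$n_anchors,
    seed = cfg$seed,
    n_clusters = bundle$clusters$k,
    silhouette = bundle$clusters$silhouette,
    convergence_iteration = as.integer(bundle$convergence),
    converged = isTRUE(attr(bundle$convergence, "converged"))
  )
  jsonlite::write_json(resolved, file.path(cfg$out, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  summary_tbl <- glance(bundle$clusters)
  readr::write_tsv(summary_tbl, file.path(cfg$out, "summary.tsv"))
  invisible(cfg$out)
}

#' Package defaults, in one table
#'
#' @return A tibble of the numeric defaults used across the package.
#' @export
show_defaults <- function() {
  tibble(
    parameter = c("wl_max_k", "structure_wl_max_k", "augment (all categories)",
                  "filter_unique", "dim (cohort >= 100)", "dim (cohort < 100)",
                  "iterations", "alpha", "alpha_min", "negative",
                  "cluster threshold", "n_anchors", "duplicate_tol",
                  "convergence tol", "convergence patience"),
    value = c("3", "3", "1", "TRUE", "128", "32", "500", "0.025", "1e-4",
              "10", "0.4", "1", "0.05", "1e-3", "5")
  )
}
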