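#' Pairwise cosine distance matrix of tree embeddings
#'
#' Computes `d(i, j) = 1 - cos(v_i, v_j)`, clamped to \[0, 1\] (anti-correlated
#' vectors are reported as maximally dissimilar rather than stretching the
#' scale to 2), with an exactly zero diagonal. Duplicate and anchor rows are
#' excluded by default: they are training scaffolding, not cohort members.
#'
#' @param x A `tree2vec` model or a numeric matrix with one row per tree
#'   (rownames = tree ids).
#' @param rows For a model, `"primary"` (default) or `"all"` documents.
#' @return A symmetric `tree_dist` matrix with entries in \[0, 1\].
#' @export
cosine_distance_matrix <- function(x, rows = c("primary", "all")) {
  rows <- match.arg(rows)
  m <- if (inherits(x, "tree2vec")) {
    if (rows == "primary") primary_vectors(x) else x$doc_vectors
  } else {
    as.matrix(x)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("tree", seq_len(nrow(m)))
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) {
    abort(sprintf("zero-norm embedding for tree '%s'",
                  rownames(m)[norms == 0][1]))
  }
  cos <- (m / norms) %*% t(m / norms)
  d <- pmin(pmax(1 - cos, 0), 1)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  class(d) <- c("tree_dist", class(d))
  d
}

#' @export
print.tree_dist <- function(x, ...) {
  cat(sprintf("<tree_dist> %d trees, cosine distance in [%.3f, %.3f]\n",
              nrow(x), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

#' @method tidy tree_dist
#' @export
tidy.tree_dist <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(tree_1 = ids[idx[, 1]], tree_2 = ids[idx[, 2]],
         distance = x[idx])
}

#' Hierarchical clustering with a maximum intra-cluster distance cutoff
#'
#' Builds a Ward dendrogram on the cosine distance matrix and cuts it at the
#' coarsest flat clustering (fewest clusters) in which every cluster's
#' maximum pairwise original distance is at most `threshold`. Distance 0
#' means identical trees, so the default 0.4 groups trees sharing a clear
#' majority of their vocabulary; trees farther than the threshold from
#' everything end up as singletons.
#'
#' @param dist A `tree_dist` (or plain symmetric) matrix.
#' @param threshold Maximum allowed intra-cluster pairwise distance, in
#'   (0, 1\].
#' @param linkage `"ward"` (default) or `"average"`.
#' @return A `tree_clusters` object: `assignments` tibble (tree_id, cluster;
#'   indices contiguous from 1 in dendrogram-cut order), `k`, `threshold`,
#'   `silhouette` (mean silhouette width, `NA` for a single cluster), the
#'   `hclust` object and the distance matrix.
#' @export
hierarchical_clusters <- function(dist, threshold = 0.4,
                                  linkage = c("ward", "average")) {
  linkage <- match.arg(linkage)
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  d <- as.matrix(dist)
  n <- nrow(d)
  ids <- rownames(d) %||% paste0("tree", seq_len(n))
  hc <- hclust(as.dist(d), method = c(ward = "ward.D2", average = "average")[[linkage]])
  assignment <- NULL
  for (k in seq_len(n)) {
    cl <- cutree(hc, k = k)
    ok <- all(vapply(split(seq_len(n), cl), function(members) {
      length(members) < 2L || max(d[members, members]) <= threshold
    }, logical(1)))
    if (ok) {
      assignment <- cl
      break
    }
  }
  k <- max(assignment)
  sil <- if (k < 2L) {
    NA_real_
  } else if (k == n) {
    0  # all singletons: every width is 0 by convention
  } else {
    mean(cluster::silhouette(assignment, dmatrix = d)[, "sil_width"])
  }
  structure(list(
    assignments = tibble(tree_id = ids, cluster = unname(assignment)),
    k = max(assignment), threshold = threshold, silhouette = sil,
    hclust = hc, linkage = linkage, dist = d
  ), class = "tree_clusters")
}

#' @export
print.tree_clusters <- function(x, ...) {
  cat(sprintf("<tree_clusters> %d trees in %d clusters (threshold %.2f, %s linkage)\n",
              nrow(x$assignments), x$k, x$threshold, x$linkage))
  if (!is.na(x$silhouette)) cat(sprintf("  mean silhouette %.3f\n", x$silhouette))
  invisible(x)
}

#' @method tidy tree_clusters
#' @export
tidy.tree_clusters <- function(x, ...) x$assignments

#' @method glance tree_clusters
#' @export
glance.tree_clusters <- function(x, ...) {
  tibble(n_trees = nrow(x$assignments), n_clusters = x$k,
         threshold = x$threshold, linkage = x$linkage,
         silhouette = x$silhouette)
}

#' Mean silhouette width of a clustering on a precomputed distance matrix
#'
#' Standard silhouette: for each tree, `s(i) = (b(i) - a(i)) / max(a(i),
#' b(i))` with `a(i)` the mean distance to its own cluster and `b(i)` the
#' smallest mean distance to another cluster; singletons score 0.
#'
#' @param dist A symmetric distance matrix.
#' @param assignments A tibble (tree_id, cluster), a named vector, or a bare
#'   integer vector in row order.
#' @return Mean silhouette width in \[-1, 1\]. A single cluster has no
#'   silhouette: this is signaled as a classed error
#'   (`oncotreevec_single_cluster`), not a numeric return.
#' @export
silhouette_score <- function(dist, assignments) {
  d <- as.matrix(dist)
  cl <- normalize_assignments(assignments, rownames(d) %||% seq_len(nrow(d)))
  if (length(unique(cl)) < 2L) {
    abort("silhouette is undefined for a single cluster",
          class = "oncotreevec_single_cluster")
  }
  if (length(unique(cl)) == nrow(d)) return(0)
  mean(cluster::silhouette(as.integer(factor(cl)), dmatrix = d)[, "sil_width"])
}

normalize_assignments <- function(assignments, ids) {
  if (is.data.frame(assignments)) {
    cl <- assignments$cluster[match(ids, assignments$tree_id)]
    if (anyNA(cl)) abort("assignments do not cover all trees")
    return(cl)
  }
  if (!is.null(names(assignments))) {
    cl <- assignments[match(ids, names(assignments))]
    if (anyNA(cl)) abort("assignments do not cover all trees")
    return(unname(cl))
  }
  if (length(assignments) != length(ids)) abort("assignments do not cover all trees")
  assignments
}

#' Grid search for vocabulary/embedding parameters by silhouette
#'
#' Runs the full pipeline (vocabulary, training, clustering at the default
#' cutoff) for every grid point and ranks configurations by the mean
#' silhouette of the resulting clustering, descending; ties are broken by
#' smaller embedding dimension, then smaller WL size (prefer the simpler
#' model). Grid points whose clustering collapses to a single cluster have
#' no silhouette and rank last, flagged.
#'
#' @param cohort A cohort tibble.
#' @param grid A tibble with columns `wl_max_k`, `dim`, and optionally
#'   `augment` (list-column of named weight vectors) and `filter_override`
#'   (list-column).
#' @param params Base [train_params()] (dim is overridden per grid point).
#' @param threshold Clustering cutoff.
#' @param n_anchors Anchors per corpus.
#' @param seed Seed used for corpus assembly and training.
#' @return The grid tibble with `silhouette`, `n_clusters`, `single_cluster`,
#'   ranked best first.
#' @export
recommend_parameters <- function(cohort, grid, params = train_params(),
                                 threshold = 0.4, n_anchors = 1L, seed = 1L) {
  if (!nrow(grid)) abort("empty parameter grid")
  ids <- unique(cohort$tree_id)
  res <- purrr::map(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    cfg <- vocab_config(
      wl_max_k = row$wl_max_k,
      augment = if ("augment" %in% names(grid)) row$augment[[1]] else NULL,
      filter_override = if ("filter_override" %in% names(grid)) row$filter_override[[1]] else NULL
    )
    docs <- suppressWarnings(build_corpus(cohort, cfg))
    corpus <- prepare_training_corpus(docs, tree_ids = ids,
                                      n_anchors = n_anchors, seed = seed)
    p <- params
    p$dim <- as.integer(row$dim)
    p$seed <- as.integer(seed)
    model <- train_embeddings(corpus, p)
    cl <- hierarchical_clusters(cosine_distance_matrix(model), threshold)
    tibble(silhouette = cl$silhouette, n_clusters = cl$k,
           single_cluster = cl$k < 2L)
  })
  out <- bind_cols(grid, bind_rows(res))
  out[order(out$single_cluster, -ifelse(is.na(out$silhouette), -Inf, out$silhouette),
            out$dim, out$wl_max_k), ]
}

#' Dominant vocabulary words of each cluster
#'
#' Summarizes what each cluster shares: for every cluster and word, the
#' fraction of the cluster's trees whose document contains the word, sorted
#' by fraction (descending), then canonical category order, then token.
#' Fraction-1 words of a non-structure category are the patterns that define
#' the cluster.
#'
#' @param clusters A `tree_clusters` object (or an assignments tibble).
#' @param documents A document tibble covering the clustered trees.
#' @param min_fraction Drop words below this containment fraction.
#' @return A tibble `cluster`, `category`, `token`, `n_trees`, `fraction`.
#' @export
dominant_words <- function(clusters, documents, min_fraction = 0.5) {
  assignments <- if (inherits(clusters, "tree_clusters")) clusters$assignments else clusters
  missing <- setdiff(unique(documents$tree_id), assignments$tree_id)
  if (length(missing)) {
    documents <- documents[!documents$tree_id %in% missing, ]
  }
  sizes <- count(assignments, .data$cluster, name = "size")
  documents %>%
    inner_join(assignments, by = "tree_id") %>%
    distinct(.data$cluster, .data$tree_id, .data$category, .data$token) %>%
    count(.data$cluster, .data$category, .data$token, name = "n_trees") %>%
    left_join(sizes, by = "cluster") %>%
    mutate(fraction = .data$n_trees / .data$size) %>%
    filter(.data$fraction >= min_fraction) %>%
    arrange(.data$cluster, desc(.data$fraction),
            category_rank(.data$category), .data$token) %>%
    select("cluster", "category", "token", "n_trees", "fraction")
}

#' Clustered heatmap of a tree distance matrix
#'
#' @param object A `tree_dist` matrix.
#' @param clusters Optional `tree_clusters` for ordering; defaults to a Ward
#'   dendrogram order of `object`.
#' @param ... Unused.
#' @return A ggplot tile heatmap in dendrogram order.
#' @method autoplot tree_dist
#' @export
autoplot.tree_dist <- function(object, clusters = NULL, ...) {
  d <- as.matrix(object)
  ord <- if (!is.null(clusters)) {
    clusters$hclust$order
  } else {
    hclust(as.dist(d), method = "ward.D2")$order
  }
  ids <- rownames(d)[ord]
  df <- tidyr::expand_grid(tree_1 = ids, tree_2 = ids)
  df$distance <- d[cbind(df$tree_1, df$tree_2)]
  df$tree_1 <- factor(df$tree_1, levels = ids)
  df$tree_2 <- factor(df$tree_2, levels = rev(ids))
  ggplot2::ggplot(df, ggplot2::aes(.data$tree_1, .data$tree_2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cosine\ndistance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}
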