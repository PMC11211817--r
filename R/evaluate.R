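#' Expected similarity rank ordering
#'
#' A rank spec names a reference tree and an ordered list of ranks (rank 1 =
#' highest expected similarity to the reference; ties share a rank).
#'
#' @param reference Reference tree id.
#' @param ranks List of character vectors of tree ids, most similar first.
#' @return A `rank_spec` list.
#' @export
rank_spec <- function(reference, ranks) {
  ids <- unlist(ranks)
  if (anyDuplicated(ids)) abort("tree ids must be unique across ranks")
  if (reference %in% ids) abort("reference must not appear in the ranks")
  structure(list(reference = reference, ranks = ranks), class = "rank_spec")
}

#' Build a rank spec from designed match counts
#'
#' Trees with equal match count w.r.t. the reference share a rank; ranks are
#' ordered by decreasing count.
#'
#' @param reference Reference tree id.
#' @param counts Named vector (names = tree ids) of expected match counts.
#' @return A `rank_spec`.
#' @export
rank_spec_from_counts <- function(reference, counts) {
  counts <- counts[names(counts) != reference]
  lev <- sort(unique(counts), decreasing = TRUE)
  rank_spec(reference, lapply(lev, function(v) names(counts)[counts == v]))
}

#' Mean one-sided deviation from an expected similarity rank ordering
#'
#' For every tree at rank r >= 2, the violation is
#' `max(0, sim(tree) - min(sim over rank r-1))`: each similarity score
#' should be at most the minimum score of the previous (more similar) rank,
#' and slack in the right direction is not rewarded. Returns the mean
#' violation over all rank >= 2 trees; 0 exactly when the learned ordering
#' respects the designed one. Translation-invariant in the similarities.
#'
#' @param similarities Named numeric vector of similarities to the reference
#'   tree (must cover every id in the spec).
#' @param spec A [rank_spec()].
#' @return Mean violation (>= 0).
#' @export
rank_deviation <- function(similarities, spec) {
  ids <- unlist(spec$ranks)
  if (!all(ids %in% names(similarities))) {
    abort(sprintf("missing similarity for tree '%s'",
                  setdiff(ids, names(similarities))[1]))
  }
  if (length(spec$ranks) < 2L) return(0)
  violations <- numeric(0)
  for (r in 2:length(spec$ranks)) {
    prev_min <- min(similarities[spec$ranks[[r - 1L]]])
    v <- pmax(0, similarities[spec$ranks[[r]]] - prev_min)
    violations <- c(violations, v)
  }
  mean(violations)
}

#' Cosine similarity matrix from a distance matrix
#'
#' @param dist A `tree_dist` matrix.
#' @return `1 - dist` (similarity 1 = identical).
#' @export
similarity_matrix <- function(dist) 1 - as.matrix(dist)

#' Per-group rank deviation for a grouped cohort (dataset-I style)
#'
#' For each group, orders the trees by their designed rank (decreasing
#' vocabulary intersection with the group's start tree), computes
#' [rank_deviation()] of the cosine similarities to the start tree, then
#' averages within groups and across groups.
#'
#' @param dist A `tree_dist` over the cohort.
#' @param groups Truth tibble with `tree_id`, `group`, `rank` (rank 0 =
#'   start/reference tree of its group).
#' @return A list: `mean_deviation` (scalar average over groups) and
#'   `per_group` tibble.
#' @export
grouped_rank_deviation <- function(dist, groups) {
  sim <- similarity_matrix(dist)
  per_group <- groups %>%
    group_by(.data$group) %>%
    summarise(deviation = {
      g <- dplyr::pick(dplyr::everything())
      ref <- g$tree_id[g$rank == 0L]
      others <- g[g$rank > 0L, ]
      spec <- rank_spec(ref, as.list(others$tree_id[order(others$rank)]))
      rank_deviation(sim[ref, ], spec)
    }, .groups = "drop")
  list(mean_deviation = mean(per_group$deviation), per_group = per_group)
}

#' Per-tree rank deviation against designed match counts (dataset-II style)
#'
#' Treats every tree in turn as the reference: the other trees are ranked by
#' their designed match count with it (ties share a rank), the one-sided
#' rank violations of the learned cosine similarities are averaged per tree,
#' and the per-tree deviations are averaged over the cohort.
#'
#' @param dist A `tree_dist`.
#' @param match_counts Tibble `tree_1`, `tree_2`, `count` covering all
#'   unordered pairs.
#' @return A list: `mean_deviation` and `per_tree` tibble.
#' @export
pairwise_rank_deviation <- function(dist, match_counts) {
  sim <- similarity_matrix(dist)
  ids <- rownames(sim)
  both <- bind_rows(match_counts,
                    rename(match_counts, tree_1 = "tree_2", tree_2 = "tree_1"))
  per_tree <- purrr::map_dbl(ids, function(id) {
    cnt <- both[both$tree_1 == id, ]
    counts <- stats::setNames(cnt$count, cnt$tree_2)
    spec <- rank_spec_from_counts(id, counts)
    rank_deviation(sim[id, ], spec)
  })
  list(mean_deviation = mean(per_tree),
       per_tree = tibble(tree_id = ids, deviation = per_tree))
}

#' Antidiagonal consistency: spread of distances at equal match count
#'
#' Pairs of trees designed to share the same number of matching nodes should
#' be equally distant. Groups all pairs by their designed match count,
#' takes the population standard deviation of the learned cosine distances
#' within each group (singleton groups contribute 0), and returns the mean
#' over groups. 0 exactly when distance is a pure function of match count.
#'
#' @param dist A `tree_dist`.
#' @param match_counts Tibble `tree_1`, `tree_2`, `count` covering all
#'   off-diagonal pairs.
#' @return A list: `mean_std` (scalar), `per_group` tibble (count, n_pairs,
#'   std, and the sample standard deviation for reference).
#' @export
antidiagonal_std <- function(dist, match_counts) {
  d <- as.matrix(dist)
  needed <- union(match_counts$tree_1, match_counts$tree_2)
  absent <- setdiff(needed, rownames(d))
  if (length(absent)) {
    abort(sprintf("match_counts tree '%s' absent from dist", absent[1]))
  }
  per_group <- match_counts %>%
    mutate(distance = d[cbind(.data$tree_1, .data$tree_2)]) %>%
    group_by(.data$count) %>%
    summarise(n_pairs = n(),
              std = sqrt(mean((.data$distance - mean(.data$distance))^2)),
              sample_std = ifelse(n() > 1L, sd(.data$distance), 0),
              .groups = "drop")
  list(mean_std = mean(per_group$std), per_group = per_group)
}

#' Silhouette of the intended-pair separation (dataset-III style)
#'
#' Silhouette over all trees on the given distance matrix, with each
#' intended pair as its own cluster: a perfectly learned cohort has each
#' matching pair at distance ~0 from itself and far from everything else
#' (silhouette near 1 for those trees), while the trees of a non-matching
#' pair are as far from their own partner as from the rest (silhouette near
#' or below 0).
#'
#' @param dist A `tree_dist`.
#' @param pairs Truth tibble with `tree_id`, `pair_id`.
#' @return Mean silhouette width.
#' @export
pair_silhouette <- function(dist, pairs) {
  silhouette_score(dist, tibble(tree_id = pairs$tree_id,
                                cluster = as.integer(pairs$pair_id)))
}

#' Compare tree distance matrices on an intended-pair cohort
#'
#' For this package's distance matrix and any externally computed ones (same
#' tree ids), reports per metric: the distance of every intended matching
#' pair, the two non-matching pairs, the mean distance over all "negative"
#' pairs (trees not belonging to the same intended pair) and the
#' intended-pair silhouette of [pair_silhouette()].
#'
#' @param dist_ours A `tree_dist` on the paired cohort.
#' @param truth Truth list of [simulate_dataset3()] (or its `pairs` tibble).
#' @param dist_external Named list of external distance matrices (CSV
#'   matrices read with [read_distance_csv()], same ids).
#' @return A tibble, one row per metric: `metric`, one column per pair
#'   (named by its category), `negatives` (mean distance over all pairs of
#'   trees not forming an intended pair), `separation_silhouette` (silhouette
#'   of the one-dimensional two-group split {matching-pair distances} vs
#'   {negative distances}; 1 for an ideal metric) and `pair_silhouette`
#'   (the intended-pair clustering silhouette of [pair_silhouette()]).
#' @export
compare_metrics <- function(dist_ours, truth, dist_external = list()) {
  pairs <- if (is.data.frame(truth)) truth else truth$pairs
  mats <- c(list(oncotreevec = as.matrix(dist_ours)),
            lapply(dist_external, as.matrix))
  ids <- pairs$tree_id
  for (nm in names(mats)) {
    if (!all(ids %in% rownames(mats[[nm]]))) {
      abort(sprintf("metric '%s': missing tree id '%s'", nm,
                    setdiff(ids, rownames(mats[[nm]]))[1]))
    }
  }
  wide <- pairs %>%
    group_by(.data$pair_id, .data$category, .data$matching) %>%
    summarise(a = .data$tree_id[1], b = .data$tree_id[2], .groups = "drop") %>%
    arrange(.data$pair_id)
  col_names <- make.unique(tolower(wide$category), sep = "_")
  rows <- purrr::imap(mats, function(m, nm) {
    pair_d <- m[cbind(wide$a, wide$b)]
    same <- outer(pairs$pair_id[match(rownames(m), pairs$tree_id)],
                  pairs$pair_id[match(colnames(m), pairs$tree_id)], "==")
    neg_d <- m[upper.tri(m) & !same]
    matching_d <- pair_d[wide$matching]
    nonmatching_d <- pair_d[!wide$matching]
    bind_cols(tibble(metric = nm),
              tibble::as_tibble_row(stats::setNames(as.list(pair_d), col_names)),
              tibble(negatives = mean(neg_d),
                     separation_silhouette = separation_silhouette(
                       matching_d, c(nonmatching_d, neg_d)),
                     pair_silhouette = pair_silhouette(m[ids, ids], pairs)))
  })
  bind_rows(rows)
}

# Silhouette of a one-dimensional two-group split of distance values.
separation_silhouette <- function(group_a, group_b) {
  x <- c(group_a, group_b)
  cl <- rep(1:2, c(length(group_a), length(group_b)))
  mean(cluster::silhouette(cl, dmatrix = abs(outer(x, x, "-")))[, "sil_width"])
}

#' Read / write a labeled distance matrix CSV
#'
#' Square CSV with tree ids as both header and first column, the layout this
#' package writes; externally computed matrices in the same layout can be
#' compared with [compare_metrics()].
#'
#' @param path CSV path.
#' @return A `tree_dist` matrix.
#' @export
read_distance_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_double(), tree_id = readr::col_character()))
  m <- as.matrix(df[, -1])
  rownames(m) <- df$tree_id
  if (!identical(rownames(m), colnames(m))) {
    abort("distance CSV rows and columns must carry the same tree ids")
  }
  class(m) <- c("tree_dist", class(m))
  m
}

#' @rdname read_distance_csv
#' @param dist A `tree_dist` matrix to write.
#' @export
write_distance_csv <- function(dist, path) {
  m <- as.matrix(dist)
  df <- bind_cols(tibble(tree_id = rownames(m)), as_tibble(m))
  readr::write_csv(df, path)
  invisible(path)
}
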