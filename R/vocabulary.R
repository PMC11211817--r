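#' Vocabulary extraction configuration
#'
#' Controls which categories of tree words are extracted, how deep the
#' Weisfeiler-Lehman (WL) relabeling iterates, per-category augmentation
#' weights and the unique-word filtering rule.
#'
#' Categories: `NODE` (individual non-root labels, i.e. neighborhoods of size
#' 0), `NEIGHBORHOOD` (WL tokens of sizes 1..`wl_max_k` on the labeled tree),
#' `ROOT_CHILD` (`root>X` for each child of the germline root), `DIRECT_EDGE`
#' (`X>Y` parent-child pairs among mutations), `PATH_PAIR` (`X>>Y`
#' ancestor-descendant pairs at path distance >= 2), `EXCLUSIVE_PAIR`
#' (`X||Y` pairs on different branches) and `STRUCTURE` (WL tokens of sizes
#' 1..`structure_wl_max_k` on the label-stripped tree, root included).
#'
#' @param wl_max_k Largest labeled WL neighborhood size (0 disables
#'   `NEIGHBORHOOD` words). Capped at 5; in practice 3 distinguishes all
#'   matches that occur in real cohorts.
#' @param structure_wl_max_k Largest label-free WL size (>= 1).
#' @param augment Named integer vector of per-category multiplicities (names
#'   among the categories above). Weight 0 disables a category; weight k
#'   multiplies every surviving word count of that category by k, increasing
#'   its pull during embedding learning. Unnamed categories default to 1.
#' @param filter_unique Drop words whose document frequency across the cohort
#'   is 1 (no possible match, they only dilute the signal). Default `TRUE`.
#' @param filter_override Named logical vector overriding `filter_unique` per
#'   category, e.g. `c(NODE = FALSE)` to keep unique node labels while still
#'   filtering pairwise-relation words.
#' @param wl_undirected Aggregate over the undirected neighborhood (parent and
#'   children) instead of children only; provided for compatibility with
#'   whole-graph embedding tools that ignore edge direction. Default `FALSE`:
#'   mutation order is directional.
#' @return A `vocab_config` object (a validated list).
#' @export
vocab_config <- function(wl_max_k = 3L, structure_wl_max_k = 3L,
                         augment = NULL, filter_unique = TRUE,
                         filter_override = NULL, wl_undirected = FALSE) {
  wl_max_k <- as.integer(wl_max_k)
  structure_wl_max_k <- as.integer(structure_wl_max_k)
  if (is.na(wl_max_k) || wl_max_k < 0L || wl_max_k > 5L) {
    abort("wl_max_k must be an integer in 0..5")
  }
  if (is.na(structure_wl_max_k) || structure_wl_max_k < 1L || structure_wl_max_k > 5L) {
    abort("structure_wl_max_k must be an integer in 1..5")
  }
  aug <- stats::setNames(rep(1L, length(VOCAB_CATEGORIES)), VOCAB_CATEGORIES)
  if (!is.null(augment)) {
    bad <- setdiff(names(augment), VOCAB_CATEGORIES)
    if (length(bad)) abort(sprintf("unknown vocabulary category '%s'", bad[1]))
    if (any(augment < 0) || any(augment != floor(augment))) {
      abort("augment weights must be non-negative integers")
    }
    aug[names(augment)] <- as.integer(augment)
  }
  filt <- stats::setNames(rep(isTRUE(filter_unique), length(VOCAB_CATEGORIES)),
                          VOCAB_CATEGORIES)
  if (!is.null(filter_override)) {
    bad <- setdiff(names(filter_override), VOCAB_CATEGORIES)
    if (length(bad)) abort(sprintf("unknown vocabulary category '%s'", bad[1]))
    filt[names(filter_override)] <- as.logical(filter_override)
  }
  structure(list(wl_max_k = wl_max_k, structure_wl_max_k = structure_wl_max_k,
                 augment = aug, filter = filt, wl_undirected = wl_undirected),
            class = "vocab_config")
}

#' @export
print.vocab_config <- function(x, ...) {
  cat("<vocab_config>\n")
  cat("  wl_max_k:", x$wl_max_k, " structure_wl_max_k:", x$structure_wl_max_k,
      " wl_undirected:", x$wl_undirected, "\n")
  cat("  augment:", paste0(names(x$augment), "=", x$augment, collapse = " "), "\n")
  cat("  filter_unique:", paste0(names(x$filter), "=", x$filter, collapse = " "), "\n")
  invisible(x)
}

# Strip the WL-size suffix: NEIGHBORHOOD_2 -> NEIGHBORHOOD, STRUCTURE_1 -> STRUCTURE.
base_category <- function(category) sub("_[0-9]+$", "", category)

# Canonical ordering of categories for reports.
category_rank <- function(category) {
  base <- base_category(category)
  k <- suppressWarnings(as.integer(sub("^.*_([0-9]+)$", "\\1", category)))
  match(base, c(VOCAB_CATEGORIES, "ANCHOR")) * 100L + ifelse(is.na(k), 0L, k)
}

#' Weisfeiler-Lehman relabeling of one tree
#'
#' Iteratively encodes the rooted (descendant-directed) subtree of depth `k`
#' below every node as a canonical string token: `token_0(v)` is the node
#' label (or the constant placeholder when `use_labels = FALSE`), and
#' `token_k(v)` combines `token_{k-1}(v)` with the sorted multiset of its
#' children's `token_{k-1}`. Tokens are therefore deterministic and invariant
#' under child reordering, and two nodes in different trees get equal
#' iteration-k tokens exactly when their depth-k labeled (or label-stripped)
#' subtrees are isomorphic.
#'
#' @param tree A single-tree tibble.
#' @param iterations Number of WL iterations (>= 1).
#' @param use_labels Use node labels (`TRUE`) or strip them (`FALSE`).
#' @param undirected Aggregate parent as well as children.
#' @return A tibble `node_id`, `iteration` (1..`iterations`), `token`.
#' @export
wl_relabel <- function(tree, iterations, use_labels = TRUE, undirected = FALSE) {
  stopifnot(iterations >= 1L)
  n <- nrow(tree)
  idx <- match(tree$parent_id, tree$node_id)  # NA for root
  nbrs <- vector("list", n)
  for (v in seq_len(n)) {
    ch <- which(idx == v)
    if (undirected && !is.na(idx[v])) ch <- c(ch, idx[v])
    nbrs[[v]] <- ch
  }
  tok <- if (use_labels) tree$label else rep("*", n)
  out <- vector("list", iterations)
  for (k in seq_len(iterations)) {
    tok <- vapply(seq_len(n), function(v) {
      paste0(tok[v], "(", paste(sort(tok[nbrs[[v]]]), collapse = ","), ")")
    }, character(1))
    out[[k]] <- tibble(node_id = tree$node_id, iteration = k, token = tok)
  }
  bind_rows(out)
}

#' Pairwise subclone relations of one tree
#'
#' Enumerates the biologically meaningful node-pair words: `ROOT_CHILD`
#' (`root>X`, the tumor-initiating events directly below the germline),
#' `DIRECT_EDGE` (`X>Y` for each mutation-to-mutation edge: direct clonal
#' co-occurrence), `PATH_PAIR` (`X>>Y` for ancestor/descendant mutations at
#' path distance >= 2: indirect co-occurrence on one lineage) and
#' `EXCLUSIVE_PAIR` (`X||Y`, unordered with `X < Y`, for mutations on
#' different branches: clonal exclusivity). The root participates only in
#' `ROOT_CHILD`, where its label is dropped so that primary events compare
#' across cohorts. Every unordered pair of distinct mutations lands in
#' exactly one of `DIRECT_EDGE`, `PATH_PAIR` or `EXCLUSIVE_PAIR`.
#'
#' @param tree A single-tree tibble.
#' @return A tibble `category`, `token`.
#' @export
extract_pair_relations <- function(tree) {
  idx <- match(tree$parent_id, tree$node_id)
  root <- which(is.na(idx))
  lab <- tree$label
  non_root <- setdiff(seq_len(nrow(tree)), root)
  res <- list()
  root_kids <- lab[which(idx == root)]
  res$ROOT_CHILD <- if (length(root_kids)) paste0("root>", root_kids) else character(0)
  # strict ancestor chains (non-root ancestors only), with path distances
  anc <- lapply(seq_len(nrow(tree)), function(v) {
    out <- integer(0); cur <- idx[v]
    while (!is.na(cur)) { out <- c(out, cur); cur <- idx[cur] }
    out
  })
  direct <- character(0); path <- character(0)
  for (v in non_root) {
    a <- anc[[v]]
    a <- a[a != root]
    if (length(a) >= 1L) direct <- c(direct, paste0(lab[a[1]], ">", lab[v]))
    if (length(a) >= 2L) path <- c(path, paste0(lab[a[-1]], ">>", lab[v]))
  }
  res$DIRECT_EDGE <- direct
  res$PATH_PAIR <- path
  excl <- character(0)
  if (length(non_root) >= 2L) {
    comparable <- new.env()
    for (v in non_root) {
      for (a in setdiff(anc[[v]], root)) {
        assign(paste(min(a, v), max(a, v)), TRUE, envir = comparable)
      }
    }
    pairs <- utils::combn(non_root, 2L)
    for (j in seq_len(ncol(pairs))) {
      u <- pairs[1, j]; v <- pairs[2, j]
      if (!exists(paste(min(u, v), max(u, v)), envir = comparable)) {
        lu <- lab[u]; lv <- lab[v]
        excl <- c(excl, paste0(min(lu, lv), "||", max(lu, lv)))
      }
    }
  }
  res$EXCLUSIVE_PAIR <- excl
  bind_rows(purrr::imap(res, ~ tibble(category = .y, token = .x)))
}

#' Decompose one tree into its vocabulary document
#'
#' Builds the raw (unfiltered, unaugmented) multiset of category-tagged words
#' describing a tree: individual non-root labels, labeled WL neighborhoods of
#' sizes 1..`wl_max_k` around every mutation, the four pairwise-relation
#' categories, and label-free structure words of sizes
#' 1..`structure_wl_max_k` around every node including the root. Categories
#' with augmentation weight 0 are omitted.
#'
#' @param tree A single-tree tibble.
#' @param config A [vocab_config()].
#' @return A tibble `tree_id`, `category`, `token`, `count` (occurrences).
#' @export
extract_document <- function(tree, config = vocab_config()) {
  stopifnot(inherits(config, "vocab_config"))
  aug <- config$augment
  idx <- match(tree$parent_id, tree$node_id)
  root <- which(is.na(idx))
  non_root <- setdiff(seq_len(nrow(tree)), root)
  parts <- list()
  if (aug[["NODE"]] > 0L && length(non_root)) {
    parts$node <- tibble(category = "NODE", token = tree$label[non_root])
  }
  if (aug[["NEIGHBORHOOD"]] > 0L && config$wl_max_k >= 1L && length(non_root)) {
    wl <- wl_relabel(tree, config$wl_max_k, use_labels = TRUE,
                     undirected = config$wl_undirected)
    wl <- wl[wl$node_id %in% tree$node_id[non_root], ]
    parts$nbhd <- tibble(category = paste0("NEIGHBORHOOD_", wl$iteration),
                         token = wl$token)
  }
  pr <- extract_pair_relations(tree)
  pr <- pr[aug[pr$category] > 0L, ]
  parts$pairs <- pr
  if (aug[["STRUCTURE"]] > 0L) {
    st <- wl_relabel(tree, config$structure_wl_max_k, use_labels = FALSE,
                     undirected = config$wl_undirected)
    parts$struct <- tibble(category = paste0("STRUCTURE_", st$iteration),
                           token = st$token)
  }
  words <- bind_rows(parts)
  if (!nrow(words)) {
    return(tibble(tree_id = character(), category = character(),
                  token = character(), count = integer()))
  }
  words %>%
    count(.data$category, .data$token, name = "count") %>%
    mutate(tree_id = tree$tree_id[1], .before = 1L) %>%
    mutate(count = as.integer(.data$count))
}

#' Build the filtered, augmented corpus of tree documents
#'
#' Extracts a document per tree, then (1) drops every word whose document
#' frequency across the original cohort is 1 (for the categories where
#' unique-word filtering is enabled) — an unmatched word cannot pull any two
#' trees together and only dilutes rare matches — and (2) multiplies the
#' surviving counts by the per-category augmentation weights. A tree whose
#' document becomes empty is kept in the cohort (it will embed as matching
#' nothing) with a warning.
#'
#' @param cohort A cohort tibble (>= 2 trees).
#' @param config A [vocab_config()].
#' @return A tibble `tree_id`, `category`, `token`, `count`. Deterministic
#'   given the cohort order.
#' @export
build_corpus <- function(cohort, config = vocab_config()) {
  ids <- unique(cohort$tree_id)
  if (length(ids) < 2L) abort("a corpus needs at least 2 trees")
  docs <- purrr::map(ids, ~ extract_document(cohort[cohort$tree_id == .x, ], config))
  raw <- bind_rows(docs)
  df <- raw %>%
    distinct(.data$tree_id, .data$category, .data$token) %>%
    count(.data$category, .data$token, name = "df")
  out <- raw %>%
    left_join(df, by = c("category", "token")) %>%
    filter(.data$df > 1L | !config$filter[base_category(.data$category)]) %>%
    select(-"df") %>%
    mutate(count = .data$count * unname(config$augment[base_category(.data$category)]))
  out <- out[out$count > 0L, ]
  empty <- setdiff(ids, unique(out$tree_id))
  if (length(empty)) {
    warn(sprintf("%d tree(s) have an empty document after filtering: %s",
                 length(empty), paste(head(empty, 5L), collapse = ", ")))
  }
  out$tree_id <- factor(out$tree_id, levels = ids)
  out <- arrange(out, .data$tree_id, category_rank(.data$category), .data$token)
  out$tree_id <- as.character(out$tree_id)
  out
}

#' Write a vocabulary dump TSV
#'
#' @param documents A document tibble from [build_corpus()] or
#'   [extract_document()].
#' @param path Output TSV path (`tree_id  category  token  count`).
#' @return `path`, invisibly.
#' @export
dump_vocabulary <- function(documents, path) {
  readr::write_tsv(documents[, c("tree_id", "category", "token", "count")], path)
  invisible(path)
}
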