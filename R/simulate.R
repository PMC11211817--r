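# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random labeled mutation tree
#'
#' Uniform random recursive attachment: nodes are added one at a time and
#' each new node picks its parent uniformly among the existing nodes, giving
#' the usual mix of chains and bushes. `shape` can force a pure chain
#' (`linear`) or a root-star (`star`).
#'
#' @param n_nodes Total number of nodes including the root (>= 1).
#' @param label_pool Labels for the non-root nodes (needs at least
#'   `n_nodes - 1`); default generates `m01`, `m02`, ...
#' @param seed Optional seed; the same seed reproduces the same tree.
#' @param shape `"random"`, `"linear"` or `"star"`.
#' @param tree_id Tree identifier.
#' @return A single-tree tibble.
#' @export
random_tree <- function(n_nodes, label_pool = NULL, seed = NULL,
                        shape = c("random", "linear", "star"),
                        tree_id = "tree") {
  shape <- match.arg(shape)
  if (n_nodes < 1L) abort("n_nodes must be >= 1")
  if (is.null(label_pool)) {
    label_pool <- sprintf("m%02d", seq_len(max(n_nodes - 1L, 1L)))
  }
  if (length(unique(label_pool)) < n_nodes - 1L) {
    abort("label_pool has fewer unique labels than non-root nodes")
  }
  build <- function() {
    parent <- rep(NA_integer_, n_nodes)
    if (n_nodes > 1L) {
      for (v in 2:n_nodes) {
        parent[v] <- switch(shape,
          random = sample.int(v - 1L, 1L),
          linear = v - 1L,
          star = 1L
        )
      }
    }
    tibble(tree_id = tree_id,
           node_id = seq_len(n_nodes) - 1L,
           label = c(ROOT_LABEL, label_pool[seq_len(n_nodes - 1L)]),
           parent_id = parent - 1L)
  }
  tree <- if (is.null(seed)) build() else with_seed(seed, build())
  validate_tree(tree)
  tree
}

# Canonical label-free form of a whole tree (isomorphism-invariant).
structure_signature <- function(tree) {
  depth <- max_depth(tree)
  wl <- wl_relabel(tree, iterations = max(depth, 1L), use_labels = FALSE)
  root <- tree$node_id[is.na(tree$parent_id)]
  wl$token[wl$node_id == root & wl$iteration == max(wl$iteration)]
}

max_depth <- function(tree) {
  idx <- match(tree$parent_id, tree$node_id)
  depth <- function(v) {
    d <- 0L
    while (!is.na(idx[v])) {
      v <- idx[v]
      d <- d + 1L
    }
    d
  }
  max(vapply(seq_len(nrow(tree)), depth, integer(1)))
}

# Non-root node ids ordered by undirected BFS distance from a center node,
# ties by node id: the "shrinking neighborhood" order used by dataset I.
neighborhood_order <- function(tree, center) {
  idx <- match(tree$parent_id, tree$node_id)
  n <- nrow(tree)
  adj <- vector("list", n)
  for (v in seq_len(n)) {
    if (!is.na(idx[v])) {
      adj[[v]] <- c(adj[[v]], idx[v])
      adj[[idx[v]]] <- c(adj[[idx[v]]], v)
    }
  }
  start <- match(center, tree$node_id)
  dist <- rep(NA_integer_, n)
  dist[start] <- 0L
  queue <- start
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (u in adj[[v]]) {
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        queue <- c(queue, u)
      }
    }
  }
  root <- which(is.na(tree$parent_id))
  ord <- order(dist, tree$node_id)
  tree$node_id[setdiff(ord, root)]
}

#' Synthetic dataset I: groups of trees with decreasing label overlap
#'
#' Simulates `n_groups` groups of trees with known clustering and known
#' within-group similarity rank order. Each group starts from a random tree
#' with a fresh, group-specific label set; every subsequent tree keeps the
#' same structure but retains the start tree's labels only on a shrinking
#' neighborhood around a fixed node (ordered by BFS distance from the first
#' mutation), replacing the rest with labels unique across the whole cohort.
#' Rank k therefore shares exactly `size - k` node labels with the start
#' tree, so vocabulary intersections decrease strictly with rank. The group
#' size equals the number of mutations of its start tree and is drawn
#' uniformly from `group_size_range`; structures are distinct across groups.
#'
#' @param n_groups Number of groups (>= 2).
#' @param group_size_range Inclusive range the group sizes are drawn from.
#' @param seed RNG seed.
#' @return A list with `cohort` (tibble) and `truth`: `groups` tibble
#'   (tree_id, group, rank; rank 0 = start tree) plus per-group rank specs
#'   as produced by [rank_spec()].
#' @export
simulate_dataset1 <- function(n_groups = 16L, group_size_range = c(9L, 34L),
                              seed = 1L) {
  if (n_groups < 2L) abort("n_groups must be >= 2")
  with_seed(seed, {
    seen <- character(0)
    trees <- list()
    truth <- list()
    for (g in seq_len(n_groups)) {
      s <- sample(group_size_range[1]:group_size_range[2], 1L)
      repeat {
        skeleton <- random_tree(s + 1L, tree_id = "skeleton")
        sig <- structure_signature(skeleton)
        if (!sig %in% seen) break
      }
      seen <- c(seen, sig)
      start_labels <- sprintf("g%02d_m%02d", g, seq_len(s))
      ord <- neighborhood_order(skeleton, center = skeleton$node_id[2])
      pos <- match(ord, skeleton$node_id)  # row index of each ordered node
      group_trees <- vector("list", s)
      for (k in seq_len(s) - 1L) {
        tree <- skeleton
        tree$tree_id <- sprintf("g%02d_r%02d", g, k)
        labels <- tree$label
        labels[-1] <- start_labels  # non-root rows follow node order
        if (k > 0L) {
          drop <- pos[(s - k + 1L):s]
          labels[drop] <- sprintf("g%02d_r%02d_x%02d", g, k, seq_len(k))
        }
        tree$label <- labels
        validate_tree(tree)
        group_trees[[k + 1L]] <- tree
      }
      trees <- c(trees, group_trees)
      truth[[g]] <- tibble(tree_id = sprintf("g%02d_r%02d", g, seq_len(s) - 1L),
                           group = g, rank = seq_len(s) - 1L)
    }
    truth <- bind_rows(truth)
    list(cohort = bind_rows(trees), truth = list(groups = truth))
  })
}

#' Intended vocabulary configuration for dataset I
#'
#' Labeled and label-free subtree words only (nodes, neighborhoods and
#' structures up to WL size 3); pairwise-relation categories are off, so the
#' within-group rank signal comes purely from the shared labels on a fixed
#' common structure.
#'
#' @return A [vocab_config()].
#' @export
dataset1_config <- function() {
  vocab_config(wl_max_k = 3L, structure_wl_max_k = 3L,
               augment = c(ROOT_CHILD = 0L, DIRECT_EDGE = 0L,
                           PATH_PAIR = 0L, EXCLUSIVE_PAIR = 0L))
}

#' Synthetic dataset II: a deterministic similarity ladder
#'
#' A reference chain of 50 uniquely labeled mutations plus 51 derived trees
#' `T_m` (m = 50..0) with identical structure that keep the first `m`
#' reference labels (from the root side) and carry fresh labels elsewhere.
#' Under a nodes-only vocabulary the intersection of any two documents is
#' exactly `min(a, b)`, so the full pairwise match-count matrix is known by
#' construction. Fully deterministic; no seed.
#'
#' @return A list with `cohort` (52 trees) and `truth`: `match_counts`
#'   tibble (tree_1, tree_2, count) over all unordered pairs, and `n_match`
#'   (tree_id, count) w.r.t. the reference tree.
#' @export
simulate_dataset2 <- function() {
  n <- 50L
  ref_labels <- sprintf("m%02d", seq_len(n))
  chain <- function(id, labels) {
    tibble(tree_id = id, node_id = 0:n,
           label = c(ROOT_LABEL, labels),
           parent_id = c(NA_integer_, 0:(n - 1L)))
  }
  trees <- list(chain("ref", ref_labels))
  for (m in n:0) {
    labels <- ref_labels
    if (m < n) {
      labels[(m + 1L):n] <- sprintf("t%02d_f%02d", m, seq_len(n - m))
    }
    trees[[length(trees) + 1L]] <- chain(sprintf("t%02d", m), labels)
  }
  cohort <- bind_rows(trees)
  ids <- unique(cohort$tree_id)
  m_of <- function(id) if (id == "ref") n else as.integer(sub("^t", "", id))
  pairs <- utils::combn(ids, 2L)
  match_counts <- tibble(
    tree_1 = pairs[1, ], tree_2 = pairs[2, ],
    count = pmin(vapply(pairs[1, ], m_of, integer(1)),
                 vapply(pairs[2, ], m_of, integer(1)))
  )
  n_match <- tibble(tree_id = ids, count = vapply(ids, m_of, integer(1)))
  list(cohort = cohort,
       truth = list(match_counts = match_counts, n_match = n_match))
}

#' Intended vocabulary configuration for dataset II
#'
#' Individual node labels only: every other category is discarded so the
#' pairwise vocabulary intersections equal the designed match counts. Node
#' labels are exempted from unique-word filtering here: every document then
#' holds exactly 50 words of which the designed number match, the all-fresh
#' tree T_0 trains to a consistent far position instead of staying at its
#' random initialization, and the duplicate-distance convergence diagnostic
#' remains meaningful for every tree.
#'
#' @return A [vocab_config()].
#' @export
dataset2_config <- function() {
  vocab_config(wl_max_k = 0L,
               augment = c(NEIGHBORHOOD = 0L, ROOT_CHILD = 0L,
                           DIRECT_EDGE = 0L, PATH_PAIR = 0L,
                           EXCLUSIVE_PAIR = 0L, STRUCTURE = 0L),
               filter_override = c(NODE = FALSE))
}

# Build a tree from (parent_label -> child_label) edges; root label "ROOT".
tree_from_edges <- function(tree_id, edges) {
  labels <- ROOT_LABEL
  parent <- NA_character_
  for (e in edges) {
    if (!e[1] %in% labels) abort(sprintf("unknown parent label %s", e[1]))
    labels <- c(labels, e[2])
    parent <- c(parent, e[1])
  }
  tibble(tree_id = tree_id,
         node_id = seq_along(labels) - 1L,
         label = labels,
         parent_id = match(parent, labels) - 1L)
}

#' Synthetic dataset III: one matching pattern per pair
#'
#' Thirteen pairs of trees, each sharing one precise pattern from one
#' vocabulary category, padded with labels unique to each tree so that after
#' unique-word filtering the intersection of a pair is exactly its intended
#' pattern (plus the node labels it involves):
#' one pair sharing a size-1 neighborhood (a center with two children, which
#' entails three pair-relation words: two direct edges and one exclusive
#' pair), one sharing a root-child relation, three sharing one
#' ancestor-descendant path pair, three sharing one direct edge, three
#' sharing one exclusive pair, and two non-matching pairs (same mutations in
#' reverse order; same mutations with different branching) that share no
#' relation word at all.
#'
#' @param seed Seed for the fresh padding labels (layout is fixed).
#' @return A list with `cohort` (26 trees) and `truth`: `pairs` tibble
#'   (tree_id, pair_id, category, matching).
#' @export
simulate_dataset3 <- function(seed = 1L) {
  p <- function(i, x) sprintf("p%02d_%s", i, x)
  fresh <- local({
    counter <- 0L
    function(i) {
      counter <<- counter + 1L
      sprintf("p%02d_f%03d", i, counter)
    }
  })
  pair_specs <- list()
  add <- function(category, tree_a, tree_b) {
    pair_specs[[length(pair_specs) + 1L]] <<-
      list(category = category, a = tree_a, b = tree_b)
  }

  # 1. shared size-1 neighborhood: center C with children D, E under
  #    tree-specific parents (=> shared words: NEIGHBORHOOD_1 C(D,E),
  #    DIRECT C>D, C>E, EXCLUSIVE D||E, NODE C, D, E). Fresh grandchildren
  #    keep the deeper neighborhoods of D and E tree specific.
  i <- 1L
  f1 <- fresh(i); f2 <- fresh(i); f3 <- fresh(i); f4 <- fresh(i)
  f5 <- fresh(i); f6 <- fresh(i)
  add("NEIGHBORHOOD",
      list(c("ROOT", f1), c(f1, p(i, "C")), c(p(i, "C"), p(i, "D")),
           c(p(i, "C"), p(i, "E")), c(p(i, "D"), f5), c("ROOT", f2)),
      list(c("ROOT", f3), c(f3, f4), c(f4, p(i, "C")),
           c(p(i, "C"), p(i, "D")), c(p(i, "C"), p(i, "E")),
           c(p(i, "E"), f6)))

  # 2. shared root-child relation root>R
  i <- 2L
  f1 <- fresh(i); f2 <- fresh(i); f3 <- fresh(i); f4 <- fresh(i)
  add("ROOT_CHILD",
      list(c("ROOT", p(i, "R")), c(p(i, "R"), f1), c(f1, f2)),
      list(c("ROOT", p(i, "R")), c(p(i, "R"), f3), c(p(i, "R"), f4)))

  # 3-5. shared path pair A>>B at distance >= 2, intermediates fresh
  for (i in 3:5) {
    f1 <- fresh(i); f2 <- fresh(i); f3 <- fresh(i); f4 <- fresh(i)
    add("PATH_PAIR",
        list(c("ROOT", f1), c(f1, p(i, "A")), c(p(i, "A"), f2),
             c(f2, p(i, "B"))),
        list(c("ROOT", p(i, "A")), c(p(i, "A"), f3), c(f3, f4),
             c(f4, p(i, "B"))))
  }

  # 6-8. shared direct edge A>B (the shared edge entails the size-1
  #      neighborhood of A and the leaf token of B matching as well, as in
  #      any pair of real trees sharing a terminal edge)
  for (i in 6:8) {
    f1 <- fresh(i); f2 <- fresh(i); f3 <- fresh(i)
    add("DIRECT_EDGE",
        list(c("ROOT", f1), c(f1, p(i, "A")), c(p(i, "A"), p(i, "B"))),
        list(c("ROOT", f2), c(f2, f3), c(f3, p(i, "A")),
             c(p(i, "A"), p(i, "B"))))
  }

  # 9-11. shared exclusive pair A||B on different branches
  for (i in 9:11) {
    f1 <- fresh(i); f2 <- fresh(i); f3 <- fresh(i)
    add("EXCLUSIVE_PAIR",
        list(c("ROOT", f1), c(f1, p(i, "A")), c(f1, p(i, "B"))),
        list(c("ROOT", f2), c(f2, f3), c(f3, p(i, "A")),
             c(f2, p(i, "B"))))
  }

  # 12. non-matching: same mutations in reverse temporal order (fresh side
  #     branches keep the shared labels a minority of each document)
  i <- 12L
  f1 <- fresh(i); f2 <- fresh(i); f3 <- fresh(i); f4 <- fresh(i)
  f5 <- fresh(i); f6 <- fresh(i); f7 <- fresh(i); f8 <- fresh(i)
  f9 <- fresh(i); f10 <- fresh(i)
  add("NONMATCHING_REVERSED",
      list(c("ROOT", p(i, "A")), c(p(i, "A"), p(i, "B")),
           c("ROOT", f1), c(f1, f2), c(f2, f5), c(f1, f6), c(f6, f7)),
      list(c("ROOT", p(i, "B")), c(p(i, "B"), p(i, "A")),
           c("ROOT", f3), c(f3, f4), c(f4, f8), c(f3, f9), c(f9, f10)))

  # 13. non-matching: same mutations, different branching
  i <- 13L
  f1 <- fresh(i); f2 <- fresh(i); f3 <- fresh(i); f4 <- fresh(i)
  f5 <- fresh(i); f6 <- fresh(i); f7 <- fresh(i); f8 <- fresh(i)
  add("NONMATCHING_BRANCHING",
      list(c("ROOT", f1), c(f1, p(i, "A")), c(p(i, "A"), p(i, "B")),
           c(p(i, "A"), p(i, "C")), c("ROOT", f3), c(f3, f5), c(f5, f6)),
      list(c("ROOT", f2), c(f2, p(i, "B")), c(p(i, "B"), p(i, "A")),
           c(p(i, "B"), p(i, "C")), c("ROOT", f4), c(f4, f7), c(f7, f8)))

  trees <- list()
  truth <- list()
  for (j in seq_along(pair_specs)) {
    spec <- pair_specs[[j]]
    id_a <- sprintf("pair%02d_a", j)
    id_b <- sprintf("pair%02d_b", j)
    trees[[length(trees) + 1L]] <- tree_from_edges(id_a, spec$a)
    trees[[length(trees) + 1L]] <- tree_from_edges(id_b, spec$b)
    truth[[j]] <- tibble(tree_id = c(id_a, id_b), pair_id = j,
                         category = spec$category,
                         matching = !startsWith(spec$category, "NONMATCHING"))
  }
  list(cohort = bind_rows(trees), truth = list(pairs = bind_rows(truth)))
}

#' Intended vocabulary configurations for dataset III
#'
#' With `wl_size = 0` the vocabulary is the four pairwise-relation categories
#' only, unique words filtered: after filtering, each matching pair's
#' documents contain exactly the intended shared relation words and the
#' non-matching pairs' documents are empty. With `wl_size = 1`, individual
#' node labels and size-1 neighborhoods are added and exempted from
#' unique-word filtering (only pairwise-relation categories keep the
#' non-unique-only rule), so each tree retains its unshared labels and the
#' separation is attenuated.
#'
#' @param wl_size 0 or 1.
#' @return A [vocab_config()].
#' @export
dataset3_config <- function(wl_size = 0L) {
  if (wl_size == 0L) {
    vocab_config(wl_max_k = 0L,
                 augment = c(NODE = 0L, NEIGHBORHOOD = 0L, STRUCTURE = 0L))
  } else {
    vocab_config(wl_max_k = as.integer(wl_size),
                 augment = c(STRUCTURE = 0L),
                 filter_override = c(NODE = FALSE, NEIGHBORHOOD = FALSE))
  }
}

#' Benchmark training protocols
#'
#' Fixed training parameter sets used for the three synthetic benchmarks, so
#' that scripts and tests reproduce the same runs. Dataset I (300+ trees,
#' documents of ~100+ words) trains 800 iterations with 64 sampled positions
#' per document per iteration and a learning-rate floor from 60% of training
#' (the low-rate tail lets duplicate pairs contract); dataset II trains the
#' full documents for 200 iterations at dimension 128; dataset III is a
#' small cohort trained 600 iterations at dimension 32 (the long low-rate
#' tail stabilizes the distances of the unrelated-tree pairs).
#'
#' @param seed Training seed.
#' @return A [train_params()].
#' @export
dataset1_train_params <- function(seed = 1L) {
  train_params(dim = 32L, iterations = 800L, alpha = 0.025,
               words_per_iter = 64L, checkpoint_every = 80L,
               decay_fraction = 0.6, seed = seed)
}

#' @rdname dataset1_train_params
#' @export
dataset2_train_params <- function(seed = 1L) {
  train_params(dim = 128L, iterations = 200L, alpha = 0.025,
               decay_fraction = 0.7, seed = seed)
}

#' @rdname dataset1_train_params
#' @export
dataset3_train_params <- function(seed = 1L) {
  train_params(dim = 32L, iterations = 600L, alpha = 0.025,
               decay_fraction = 0.7, seed = seed)
}
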