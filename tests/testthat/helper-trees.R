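# Tree builders and independent oracles shared across the suite.

# Build a tree tibble from (parent label -> child label) edges; the root is
# always labeled ROOT and must be named "ROOT" in the edges.
make_tree <- function(tree_id, edges) {
  labels <- "ROOT"
  parents <- NA_character_
  for (e in edges) {
    labels <- c(labels, e[2])
    parents <- c(parents, e[1])
  }
  tibble::tibble(
    tree_id = tree_id,
    node_id = seq_along(labels) - 1L,
    label = labels,
    parent_id = match(parents, labels) - 1L
  )
}

chain_tree <- function(tree_id, labels) {
  make_tree(tree_id, Map(c, c("ROOT", utils::head(labels, -1)), labels))
}

# Independent canonical form of the depth-k subtree rooted at a node:
# a direct recursion over children (not the iterative WL compression),
# sorting child forms at every level.
canonical_subtree <- function(tree, node_id, depth, use_labels = TRUE) {
  kids <- function(v) tree$node_id[!is.na(tree$parent_id) & tree$parent_id == v]
  lab <- function(v) if (use_labels) tree$label[tree$node_id == v] else "."
  rec <- function(v, d) {
    if (d == 0L) return(lab(v))
    ch <- sort(vapply(kids(v), rec, character(1), d = d - 1L))
    paste0(lab(v), "[", paste(ch, collapse = "|"), "]")
  }
  rec(node_id, depth)
}

# Exhaustive vocabulary of a small tree by brute-force enumeration:
# all depth-k canonical subtrees per node plus all pair relations read off
# ancestor sets computed independently of the package internals.
brute_force_words <- function(tree, wl_max_k = 3L, structure_max_k = 3L) {
  root <- tree$node_id[is.na(tree$parent_id)]
  non_root <- setdiff(tree$node_id, root)
  lab <- function(v) tree$label[tree$node_id == v]
  parent <- function(v) tree$parent_id[tree$node_id == v]
  ancestors <- function(v) {
    out <- integer(0)
    p <- parent(v)
    while (!is.na(p)) {
      out <- c(out, p)
      p <- parent(p)
    }
    out
  }
  words <- character(0)
  for (v in non_root) {
    words <- c(words, paste0("NODE:", lab(v)))
    for (k in seq_len(wl_max_k)) {
      words <- c(words, paste0("NB", k, ":", canonical_subtree(tree, v, k)))
    }
  }
  for (v in tree$node_id) {
    for (k in seq_len(structure_max_k)) {
      words <- c(words,
                 paste0("ST", k, ":", canonical_subtree(tree, v, k, use_labels = FALSE)))
    }
  }
  for (v in non_root) {
    anc <- setdiff(ancestors(v), root)
    if (length(anc) >= 1L) words <- c(words, paste0("DE:", lab(anc[1]), ">", lab(v)))
    if (length(anc) >= 2L) {
      for (a in anc[-1]) words <- c(words, paste0("PP:", lab(a), ">>", lab(v)))
    }
    if (identical(parent(v), root)) words <- c(words, paste0("RC:root>", lab(v)))
  }
  if (length(non_root) >= 2L) {
    pr <- utils::combn(non_root, 2L)
    for (j in seq_len(ncol(pr))) {
      u <- pr[1, j]; v <- pr[2, j]
      if (!(u %in% ancestors(v)) && !(v %in% ancestors(u))) {
        l <- sort(c(lab(u), lab(v)))
        words <- c(words, paste0("EX:", l[1], "||", l[2]))
      }
    }
  }
  words
}

# Random valid tree for property tests (uses the package generator's shape
# logic only through public API).
random_test_tree <- function(n, seed, tree_id = "t") {
  oncotreevec::random_tree(n, label_pool = sprintf("%s_m%02d", tree_id, seq_len(max(n, 2))),
                           seed = seed, tree_id = tree_id)
}

# Structural equality of two trees: same multiset of (parent label -> child
# label) edges and same label multiset, ignoring node ids.
trees_structurally_equal <- function(a, b) {
  rel <- function(tr) {
    lab <- stats::setNames(tr$label, as.character(tr$node_id))
    e <- tr[!is.na(tr$parent_id), ]
    sort(paste(lab[as.character(e$parent_id)], "->", e$label))
  }
  identical(sort(a$label), sort(b$label)) && identical(rel(a), rel(b))
}
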