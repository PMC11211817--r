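#' Parse a single mutation tree
#'
#' Reads one rooted, node-labeled mutation tree from text. Whatever label the
#' input carries on its root, it is replaced by the reserved sentinel `"ROOT"`:
#' the root stands for the germline (neutral) clone, not for a mutation, and a
#' fixed sentinel makes root-child words comparable across cohorts.
#'
#' Three formats are supported:
#' \describe{
#'   \item{`newick`}{Newick with labels on every node (internal and leaf);
#'     branch lengths, if present, are parsed and discarded. Node ids are
#'     assigned 0-based in deterministic preorder, children in input order.}
#'   \item{`json`}{An object `{"tree_id": ..., "nodes": [{"id": 0, "label":
#'     "ROOT", "parent": null}, ...]}`; node ids are taken from the input.}
#'   \item{`parent_tsv`}{A TSV with header `node_id  label  parent_id`; the
#'     root row has an empty `parent_id`.}
#' }
#'
#' @param text Character scalar with the tree text.
#' @param format One of `"newick"`, `"json"`, `"parent_tsv"`.
#' @param tree_id Tree identifier; defaults to the id carried by the input
#'   (json) or `"tree"`.
#' @return A tibble with columns `tree_id`, `node_id`, `label`, `parent_id`
#'   (one row per node, `parent_id` is `NA` for the root), validated against
#'   the mutation-tree invariants: a single root, acyclic and connected parent
#'   pointers, unique node ids and unique labels within the tree.
#' @examples
#' parse_tree("((B,C)A)ROOT;", "newick")
#' @export
parse_tree <- function(text, format = c("newick", "json", "parent_tsv"),
                       tree_id = NULL) {
  format <- match.arg(format)
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) abort("empty tree text")
  nodes <- switch(format,
    newick = parse_newick(text),
    json = parse_tree_json(text),
    parent_tsv = parse_parent_tsv(text)
  )
  id <- tree_id %||% attr(nodes, "tree_id") %||% "tree"
  new_mutation_tree(nodes, id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Assemble and validate one tree from a bare node table.
new_mutation_tree <- function(nodes, tree_id) {
  nodes <- tibble(
    node_id = as.integer(nodes$node_id),
    label = as.character(nodes$label),
    parent_id = as.integer(nodes$parent_id)
  )
  root <- which(is.na(nodes$parent_id))
  if (length(root) != 1L) {
    abort(sprintf("tree '%s': expected exactly one root, found %d (nodes %s)",
                  tree_id, length(root),
                  paste(nodes$node_id[root], collapse = ", ")))
  }
  nodes$label[root] <- ROOT_LABEL
  tree <- tibble(tree_id = as.character(tree_id), nodes)
  validate_tree(tree)
  tree
}

# Invariant checks for a single-tree tibble; errors name the offending node.
validate_tree <- function(tree) {
  id <- tree$tree_id[1]
  if (anyDuplicated(tree$node_id)) {
    abort(sprintf("tree '%s': duplicate node_id %s", id,
                  tree$node_id[duplicated(tree$node_id)][1]))
  }
  if (any(tree$node_id < 0L)) abort(sprintf("tree '%s': negative node ids", id))
  dup <- tree$label[duplicated(tree$label)]
  if (length(dup)) {
    abort(sprintf("tree '%s': duplicate label \"%s\" within one tree", id, dup[1]))
  }
  root <- tree$node_id[is.na(tree$parent_id)]
  parent <- stats::setNames(tree$parent_id, as.character(tree$node_id))
  bad <- setdiff(tree$parent_id[!is.na(tree$parent_id)], tree$node_id)
  if (length(bad)) {
    abort(sprintf("tree '%s': parent_id %s does not exist", id, bad[1]))
  }
  n <- nrow(tree)
  for (v in tree$node_id) {
    cur <- v
    for (step in seq_len(n + 1L)) {
      p <- parent[[as.character(cur)]]
      if (is.na(p)) break
      cur <- p
      if (step > n) abort(sprintf("tree '%s': cycle through node %s", id, v))
    }
    if (cur != root) abort(sprintf("tree '%s': node %s does not reach the root", id, v))
  }
  invisible(tree)
}

# Recursive-descent newick parser. General-purpose newick readers renumber
# nodes in ways that scramble label assignment on unary chains (mutation
# trees routinely have single-child internal nodes), so the dialect is
# parsed directly: labels mandatory on every node, branch lengths parsed
# and discarded, syntax errors reported with a character offset.
parse_newick <- function(text) {
  chars <- strsplit(text, "")[[1]]
  pos <- 1L
  n <- length(chars)
  fail <- function(msg, at = pos) {
    abort(sprintf("newick parse error: %s at character %d", msg, at))
  }
  skip_ws <- function() {
    while (pos <= n && grepl("^\\s$", chars[pos])) pos <<- pos + 1L
  }
  read_label <- function() {
    skip_ws()
    start <- pos
    while (pos <= n && !chars[pos] %in% c("(", ")", ",", ";", ":")) {
      pos <<- pos + 1L
    }
    label <- if (pos > start) {
      trimws(paste(chars[start:(pos - 1L)], collapse = ""))
    } else ""
    if (!nzchar(label)) fail("missing node label", start)
    if (pos <= n && chars[pos] == ":") {  # branch length: parse and discard
      pos <<- pos + 1L
      len_start <- pos
      while (pos <= n && grepl("^[0-9eE.+-]$", chars[pos])) pos <<- pos + 1L
      if (pos == len_start) fail("missing branch length after ':'")
    }
    label
  }
  labels <- character(0)
  parents <- integer(0)
  # returns the new node's id; children are visited in input order
  read_subtree <- function(parent) {
    skip_ws()
    if (pos > n) fail("unexpected end of input")
    kids_of <- integer(0)
    if (chars[pos] == "(") {
      open_at <- pos
      pos <<- pos + 1L
      repeat {
        kids_of <- c(kids_of, read_subtree(NA_integer_))
        skip_ws()
        if (pos > n) fail("unbalanced '('", open_at)
        if (chars[pos] == ",") {
          pos <<- pos + 1L
        } else if (chars[pos] == ")") {
          pos <<- pos + 1L
          break
        } else {
          fail(sprintf("unexpected '%s'", chars[pos]))
        }
      }
    }
    label <- read_label()
    my <- length(labels) + 1L
    labels[my] <<- label
    parents[my] <<- parent
    parents[kids_of] <<- my
    my
  }
  root <- read_subtree(NA_integer_)
  skip_ws()
  if (pos > n || chars[pos] != ";") fail("missing ';'")
  # assign 0-based ids in deterministic preorder
  kids <- split(seq_along(parents), factor(parents, levels = seq_along(labels)))
  preorder <- integer(0)
  walk <- function(v) {
    preorder <<- c(preorder, v)
    for (ch in kids[[v]]) walk(ch)
  }
  walk(root)
  new_of <- match(seq_along(labels), preorder)
  tibble(node_id = new_of - 1L,
         label = labels,
         parent_id = ifelse(is.na(parents), NA_integer_, new_of[parents] - 1L)) %>%
    arrange(.data$node_id)
}

parse_tree_json <- function(text) {
  rec <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  tree_record_to_nodes(rec)
}

tree_record_to_nodes <- function(rec) {
  if (is.null(rec$nodes)) abort("json parse error: missing 'nodes' field")
  nodes <- tibble(
    node_id = vapply(rec$nodes, function(x) as.integer(x$id), integer(1)),
    label = vapply(rec$nodes, function(x) as.character(x$label), character(1)),
    parent_id = vapply(rec$nodes, function(x) {
      if (is.null(x$parent)) NA_integer_ else as.integer(x$parent)
    }, integer(1))
  )
  attr(nodes, "tree_id") <- if (!is.null(rec$tree_id)) as.character(rec$tree_id) else NULL
  nodes
}

parse_parent_tsv <- function(text) {
  df <- readr::read_tsv(I(text), col_types = readr::cols(
    node_id = readr::col_integer(),
    label = readr::col_character(),
    parent_id = readr::col_integer()
  ), progress = FALSE)
  if (!all(c("node_id", "label", "parent_id") %in% names(df))) {
    abort("parent_tsv parse error: header must be 'node_id\\tlabel\\tparent_id'")
  }
  df
}

#' Serialize a single mutation tree
#'
#' Inverse of [parse_tree()]: `parse_tree(serialize_tree(t, f), f)` is
#' structurally equal to `t` (same parent relation and label multiset; node
#' ids may be renumbered for the newick format).
#'
#' @param tree A single-tree tibble as returned by [parse_tree()].
#' @param format One of `"newick"`, `"json"`, `"parent_tsv"`.
#' @return A character scalar.
#' @export
serialize_tree <- function(tree, format = c("newick", "json", "parent_tsv")) {
  format <- match.arg(format)
  validate_tree(tree)
  switch(format,
    newick = serialize_newick(tree),
    json = jsonlite::toJSON(tree_to_record(tree), auto_unbox = TRUE, null = "null"),
    parent_tsv = readr::format_tsv(tree[, c("node_id", "label", "parent_id")], na = "")
  )
}

tree_to_record <- function(tree) {
  list(
    tree_id = tree$tree_id[1],
    nodes = purrr::pmap(tree[, c("node_id", "label", "parent_id")],
                        function(node_id, label, parent_id) {
      list(id = node_id, label = label,
           parent = if (is.na(parent_id)) NULL else parent_id)
    })
  )
}

serialize_newick <- function(tree) {
  bad <- grepl("[(),;:\\s]", tree$label, perl = TRUE)
  if (any(bad)) {
    abort(sprintf("label \"%s\" contains newick metacharacters", tree$label[bad][1]))
  }
  kids <- split(tree$node_id, factor(tree$parent_id, levels = tree$node_id))
  lab <- stats::setNames(tree$label, as.character(tree$node_id))
  rec <- function(v) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch) || !length(ch)) return(lab[[as.character(v)]])
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")",
           lab[[as.character(v)]])
  }
  paste0(rec(tree$node_id[is.na(tree$parent_id)]), ";")
}

#' Read a cohort of mutation trees
#'
#' A cohort is either a directory of per-tree files (cohort order = sorted
#' file names), an explicit vector of file paths (order preserved), or a
#' single multi-record JSON file `{"name": ..., "trees": [<tree record>,
#' ...]}` (record order preserved).
#'
#' @param path Directory, files, or a multi-record JSON file.
#' @param format One of `"newick"`, `"json"`, `"parent_tsv"`. Ignored for a
#'   multi-record JSON file.
#' @return A cohort tibble (`tree_id`, `node_id`, `label`, `parent_id`), with
#'   tree order defining all downstream row orders.
#' @export
read_cohort <- function(path, format = c("newick", "json", "parent_tsv")) {
  format <- match.arg(format)
  if (length(path) == 1L && dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
  } else {
    files <- path
  }
  if (length(files) == 1L && grepl("\\.json$", files) && !dir.exists(files[1])) {
    obj <- jsonlite::fromJSON(files, simplifyVector = FALSE)
    if (!is.null(obj$trees)) {
      trees <- purrr::map(obj$trees, function(rec) {
        new_mutation_tree(tree_record_to_nodes(rec),
                          rec$tree_id %||% paste0("tree", length(rec)))
      })
      return(bind_cohort(trees))
    }
  }
  trees <- purrr::map(files, function(f) {
    id <- sub("\\.[^.]*$", "", basename(f))
    parse_tree(paste(readLines(f, warn = FALSE), collapse = "\n"), format, tree_id = id)
  })
  bind_cohort(trees)
}

bind_cohort <- function(trees) {
  ids <- purrr::map_chr(trees, ~ .x$tree_id[1])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate tree_id '%s' in cohort", ids[duplicated(ids)][1]))
  }
  bind_rows(trees)
}

#' Write a cohort to disk
#'
#' @param cohort A cohort tibble.
#' @param path Output: a `.json` path for a single multi-record file, or a
#'   directory (one file per tree) otherwise.
#' @param format Per-tree format when writing a directory.
#' @param name Cohort name stored in the multi-record JSON.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("json", "newick", "parent_tsv"),
                         name = "cohort") {
  format <- match.arg(format)
  ids <- unique(cohort$tree_id)
  if (grepl("\\.json$", path)) {
    recs <- purrr::map(ids, function(id) {
      tree_to_record(cohort[cohort$tree_id == id, ])
    })
    jsonlite::write_json(list(name = name, trees = recs), path,
                         auto_unbox = TRUE, null = "null", pretty = TRUE)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ext <- c(json = "json", newick = "nwk", parent_tsv = "tsv")[[format]]
  for (id in ids) {
    f <- file.path(path, paste0(id, ".", ext))
    writeLines(as.character(serialize_tree(cohort[cohort$tree_id == id, ], format)), f)
  }
  invisible(path)
}

#' Merge near-identical event-set labels across a cohort
#'
#' For trees whose node labels are semicolon-joined sets of genomic events
#' (e.g. copy-number clones), relabels all nodes whose event sets fall in the
#' same connected component of the graph "Jaccard distance <= threshold" with
#' a common canonical label: the lexicographically smallest member set,
#' rendered as its sorted events joined by ";". Single-linkage (connected
#' components) is used because chained near-matches should share one label.
#' Roots are untouched. Idempotent for a fixed threshold.
#'
#' @param cohort A cohort tibble; every non-root label must be a non-empty
#'   semicolon-joined event set.
#' @param threshold Jaccard distance threshold in \[0, 1\].
#' @return The relabeled cohort (re-validated; merging two nodes of the same
#'   tree into one label is an error, as in-tree labels must stay unique).
#' @export
jaccard_relabel <- function(cohort, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    abort("threshold must be a number in [0, 1]")
  }
  non_root <- !is.na(cohort$parent_id)
  raw <- cohort$label[non_root]
  if (any(!nzchar(trimws(raw)))) abort("empty event-set label")
  sets <- lapply(strsplit(raw, ";", fixed = TRUE), function(x) sort(unique(trimws(x))))
  if (any(vapply(sets, length, integer(1)) == 0L)) abort("empty event-set label")
  canon <- vapply(sets, paste, character(1), collapse = ";")
  uniq <- sort(unique(canon))
  usets <- strsplit(uniq, ";", fixed = TRUE)
  m <- length(uniq)
  edges <- integer(0)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        inter <- length(intersect(usets[[i]], usets[[j]]))
        uni <- length(union(usets[[i]], usets[[j]]))
        if (1 - inter / uni <= threshold) edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  rep_label <- vapply(seq_len(max(comp)), function(k) min(uniq[comp == k]), character(1))
  new_label <- rep_label[comp[match(canon, uniq)]]
  out <- cohort
  out$label[non_root] <- new_label
  for (id in unique(out$tree_id)) validate_tree(out[out$tree_id == id, ])
  out
}
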