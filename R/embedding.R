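#' Assemble a training corpus with duplicates and anchor documents
#'
#' The embedding model is calibrated with two kinds of control documents: a
#' verbatim duplicate of every tree document (expected cosine similarity 1;
#' their learned distance doubles as a convergence diagnostic) and at least
#' one anchor document made of fresh words appearing nowhere else (expected
#' similarity 0 to everything, pinning the "no match" end of the space).
#' Duplicates and anchors exist only for training and diagnostics; they are
#' dropped from user-facing distance matrices and clusterings.
#'
#' @param documents Filtered/augmented document tibble from [build_corpus()].
#' @param tree_ids Cohort tree ids in cohort order. Defaults to the ids
#'   present in `documents`; pass the cohort's ids explicitly when some
#'   documents may be empty (empty documents are legal and kept).
#' @param n_anchors Number of anchor documents (>= 1).
#' @param seed Seed for anchor word generation.
#' @return A `tree_corpus`: list with `origin` (doc_index, doc_id, tree_id,
#'   role in primary/duplicate/anchor), `vocab` (word_index, word, category,
#'   token, freq) and `doc_words` (per-document integer word-index vectors,
#'   counts expanded). Size is `2 * N + n_anchors`.
#' @export
prepare_training_corpus <- function(documents, tree_ids = NULL, n_anchors = 1L,
                                    seed = 1L) {
  if (is.null(tree_ids)) tree_ids <- unique(documents$tree_id)
  if (length(tree_ids) < 1L) abort("need at least one document")
  if (n_anchors < 1L) abort("n_anchors must be >= 1")
  documents <- documents[documents$tree_id %in% tree_ids, ]

  doc_len <- vapply(tree_ids, function(id) {
    sum(documents$count[documents$tree_id == id])
  }, numeric(1))
  anchor_len <- max(1L, as.integer(round(median(doc_len))))
  anchors <- purrr::map(seq_len(n_anchors), function(a) {
    tibble(tree_id = paste0("__anchor", a),
           category = "ANCHOR",
           token = sprintf("s%d_a%d_w%03d", as.integer(seed), a, seq_len(anchor_len)),
           count = 1L)
  })

  n <- length(tree_ids)
  origin <- tibble(
    doc_index = seq_len(2L * n + n_anchors),
    doc_id = c(tree_ids, paste0(tree_ids, "__dup"),
               paste0("__anchor", seq_len(n_anchors))),
    tree_id = c(tree_ids, tree_ids, rep(NA_character_, n_anchors)),
    role = c(rep("primary", n), rep("duplicate", n), rep("anchor", n_anchors))
  )

  all_words <- bind_rows(documents, bind_rows(anchors)) %>%
    mutate(word = paste0(.data$category, ":", .data$token))
  vocab <- all_words %>%
    group_by(.data$word, .data$category, .data$token) %>%
    summarise(freq = sum(.data$count), .groups = "drop") %>%
    arrange(.data$word) %>%
    mutate(freq = .data$freq * ifelse(.data$category == "ANCHOR", 1L, 2L)) %>%
    mutate(word_index = row_number(), .before = 1L)

  doc_of <- function(id, tbl) {
    rows <- tbl[tbl$tree_id == id, ]
    if (!nrow(rows)) return(integer(0))
    idx <- vocab$word_index[match(paste0(rows$category, ":", rows$token), vocab$word)]
    rep(idx, rows$count)
  }
  primary_words <- purrr::map(tree_ids, doc_of, tbl = documents)
  anchor_words <- purrr::map(anchors, ~ doc_of(.x$tree_id[1], .x))
  doc_words <- c(primary_words, primary_words, anchor_words)

  structure(list(origin = origin, vocab = vocab, doc_words = doc_words,
                 n_primary = n, seed = as.integer(seed)),
            class = "tree_corpus")
}

#' @export
print.tree_corpus <- function(x, ...) {
  cat(sprintf("<tree_corpus> %d documents (%d primaries, %d duplicates, %d anchors), %d words\n",
              nrow(x$origin), x$n_primary, x$n_primary,
              nrow(x$origin) - 2L * x$n_primary, nrow(x$vocab)))
  invisible(x)
}

#' Training hyperparameters
#'
#' @param dim Embedding dimension. Default `NULL` picks 128 for cohorts of
#'   100+ trees and 32 below that: in small cohorts a large dimension spreads
#'   the vectors too thinly and weakens cluster separation.
#' @param iterations Training iterations. One iteration is a pass over all
#'   documents in which each document contributes up to `words_per_iter`
#'   positive (document, word) pairs sampled from its word multiset.
#' @param alpha,alpha_min Initial and final learning rate: linear decay from
#'   `alpha` to the `alpha_min` floor.
#' @param decay_fraction Fraction of training over which the linear decay
#'   runs; the remainder trains at the `alpha_min` floor, letting the
#'   duplicate-pair distances contract to their expected 0 once the model
#'   has stopped moving.
#' @param negative Negative samples per positive, drawn from the unigram
#'   distribution raised to 3/4.
#' @param seed Integer seed; training is bitwise reproducible given the seed.
#' @param words_per_iter Cap on positions sampled per document per iteration
#'   (`Inf` processes every word occurrence).
#' @param checkpoint_every Checkpoint cadence in iterations; default
#'   `max(1, iterations / 100)`.
#' @return A `train_params` list.
#' @export
train_params <- function(dim = NULL, iterations = 500L, alpha = 0.025,
                         alpha_min = 1e-4, negative = 10L, seed = 1L,
                         words_per_iter = Inf, checkpoint_every = NULL,
                         decay_fraction = 0.7) {
  if (decay_fraction <= 0 || decay_fraction > 1) {
    abort("decay_fraction must be in (0, 1]")
  }
  if (!is.null(dim) && dim < 2L) abort("dim must be >= 2")
  if (iterations < 1L) abort("iterations must be >= 1")
  if (negative < 1L) abort("negative must be >= 1")
  structure(list(dim = dim, iterations = as.integer(iterations), alpha = alpha,
                 alpha_min = alpha_min, negative = as.integer(negative),
                 seed = as.integer(seed), words_per_iter = words_per_iter,
                 checkpoint_every = checkpoint_every,
                 decay_fraction = decay_fraction),
            class = "train_params")
}

#' Learn tree embeddings (PV-DBOW with negative sampling)
#'
#' Trains one vector per document (tree, duplicate or anchor) and one per
#' vocabulary word by stochastic gradient descent on the negative-sampling
#' logistic objective: each step takes a (document, word) pair from the
#' document's multiset as a positive and `negative` words drawn from the
#' unigram^0.75 noise distribution as negatives, pulling the document vector
#' towards the words it contains and away from sampled non-words. Trees
#' sharing many words therefore end up close in cosine space, in proportion
#' to the size of their vocabulary intersection.
#'
#' @param corpus A [prepare_training_corpus()] result.
#' @param params A [train_params()].
#' @return A `tree2vec` object: `doc_vectors` (documents x dim, rownames =
#'   doc ids), `word_vectors` (vocabulary x dim), `trace` (per-checkpoint
#'   iteration, mean loss, min/max pairwise document cosine distance and max
#'   duplicate-pair distance), `origin`, `vocab`, `params`.
#' @export
train_embeddings <- function(corpus, params = train_params()) {
  stopifnot(inherits(corpus, "tree_corpus"))
  if (nrow(corpus$origin) < 2L) abort("corpus must contain at least 2 documents")
  if (!nrow(corpus$vocab)) abort("corpus has an empty vocabulary")
  dim <- params$dim %||% (if (corpus$n_primary >= 100L) 128L else 32L)
  cp <- params$checkpoint_every %||% max(1L, params$iterations %/% 100L)
  n <- corpus$n_primary
  # an empty document is never updated, so its duplicate pair cannot learn
  # distance 0; keep only trainable pairs in the convergence diagnostic
  trainable <- vapply(corpus$doc_words[seq_len(n)], length, integer(1)) > 0L
  dup_pairs <- cbind(seq_len(n), n + seq_len(n))[trainable, , drop = FALSE]
  noise <- corpus$vocab$freq^0.75
  fit <- pvdbow_train_cpp(
    docs = lapply(corpus$doc_words, function(x) x - 1L),  # 0-based for C++
    noise_weights = noise, dup_pairs = dup_pairs,
    dim = as.integer(dim), iterations = params$iterations,
    alpha0 = params$alpha, alpha_min = params$alpha_min,
    negative = params$negative, seed = as.double(params$seed),
    words_per_iter = if (is.finite(params$words_per_iter))
      as.integer(params$words_per_iter) else 0L,
    checkpoint_every = as.integer(cp),
    decay_fraction = params$decay_fraction %||% 1.0)
  if (isTRUE(fit$diverged)) {
    abort("training diverged: non-finite loss; lower alpha or iterations")
  }
  doc_vectors <- fit$doc_vectors
  rownames(doc_vectors) <- corpus$origin$doc_id
  word_vectors <- fit$word_vectors
  rownames(word_vectors) <- corpus$vocab$word
  structure(list(doc_vectors = doc_vectors, word_vectors = word_vectors,
                 trace = as_tibble(fit$trace), origin = corpus$origin,
                 vocab = corpus$vocab,
                 params = utils::modifyList(unclass(params),
                                            list(dim = dim, checkpoint_every = cp))),
            class = "tree2vec")
}

#' @export
print.tree2vec <- function(x, ...) {
  n <- sum(x$origin$role == "primary")
  cat(sprintf("<tree2vec> %d trees (+%d duplicates/anchors), dim %d, %d iterations\n",
              n, nrow(x$doc_vectors) - n, ncol(x$doc_vectors),
              x$params$iterations))
  cat(sprintf("  final loss %.4f, max duplicate distance %.4f\n",
              tail(x$trace$loss, 1), tail(x$trace$max_dup_dist, 1)))
  invisible(x)
}

#' Embedding matrix of the primary trees
#'
#' @param model A `tree2vec` object.
#' @return Matrix of primary-tree vectors, rownames = tree ids (cohort order).
#' @export
primary_vectors <- function(model) {
  keep <- model$origin$role == "primary"
  m <- model$doc_vectors[keep, , drop = FALSE]
  rownames(m) <- model$origin$tree_id[keep]
  m
}

#' Exact full-softmax log likelihood of a corpus under an embedding
#'
#' Evaluates the document-embedding objective exactly: the sum over all
#' (document, word occurrence) pairs of `log Pr(w | d)`, with
#' `Pr(w | d) = exp(emb(d) . emb(w)) / sum_v exp(emb(d) . emb(v))` over the
#' whole vocabulary. Too expensive for training, but an independent oracle
#' that the negative-sampling trainer is climbing the right objective on
#' small instances.
#'
#' @param corpus A `tree_corpus`.
#' @param embeddings A `tree2vec` object, or a list with `doc_vectors` and
#'   `word_vectors` matrices dimensioned for the corpus.
#' @return The log likelihood (scalar).
#' @export
softmax_log_likelihood <- function(corpus, embeddings) {
  stopifnot(inherits(corpus, "tree_corpus"))
  if (!nrow(corpus$vocab)) abort("empty vocabulary")
  dv <- embeddings$doc_vectors
  wv <- embeddings$word_vectors
  stopifnot(nrow(dv) == length(corpus$doc_words), nrow(wv) == nrow(corpus$vocab))
  ll <- 0
  for (d in seq_along(corpus$doc_words)) {
    words <- corpus$doc_words[[d]]
    if (!length(words)) next
    logits <- as.numeric(wv %*% dv[d, ])
    lse <- max(logits) + log(sum(exp(logits - max(logits))))
    ll <- ll + sum(logits[words] - lse)
  }
  ll
}

#' Pick the convergence cutoff from a training trace
#'
#' Returns the iteration of the earliest checkpoint at which (a) the relative
#' change in mean loss stayed below `tol` over the last `patience`
#' checkpoints (the convergence curve has become steady) and (b) the maximum
#' duplicate-pair cosine distance is below `duplicate_tol` (identical trees
#' have been learned as identical). If no checkpoint qualifies, the last
#' iteration is returned with a warning and attribute `converged = FALSE`.
#'
#' @param trace The `trace` tibble of a `tree2vec` model (>= 2 checkpoints).
#' @param patience Number of consecutive steady checkpoints required.
#' @param tol Relative loss-change tolerance.
#' @param duplicate_tol Maximum allowed duplicate-pair cosine distance.
#' @return Integer iteration, with attribute `converged`.
#' @export
convergence_cutoff <- function(trace, patience = 5L, tol = 1e-3,
                               duplicate_tol = 0.05) {
  if (nrow(trace) < 2L) abort("trace needs at least 2 checkpoints")
  rel <- abs(diff(trace$loss)) / pmax(abs(head(trace$loss, -1)), 1e-12)
  for (i in seq_len(nrow(trace))) {
    if (i <= patience) next
    window <- rel[(i - patience):(i - 1L)]
    if (all(window < tol) && trace$max_dup_dist[i] < duplicate_tol) {
      return(structure(as.integer(trace$iteration[i]), converged = TRUE))
    }
  }
  warn("training trace never satisfied the convergence criteria; returning the last checkpoint")
  structure(as.integer(tail(trace$iteration, 1)), converged = FALSE)
}

#' @method tidy tree2vec
#' @export
tidy.tree2vec <- function(x, ...) {
  m <- x$doc_vectors
  colnames(m) <- paste0("e", seq_len(ncol(m)))
  bind_cols(x$origin[, c("doc_id", "tree_id", "role")], as_tibble(m))
}

#' @method glance tree2vec
#' @export
glance.tree2vec <- function(x, ...) {
  cut <- suppressWarnings(convergence_cutoff(x$trace))
  tibble(n_trees = sum(x$origin$role == "primary"),
         n_documents = nrow(x$doc_vectors),
         vocab_size = nrow(x$vocab),
         dim = ncol(x$doc_vectors),
         iterations = x$params$iterations,
         final_loss = tail(x$trace$loss, 1),
         max_dup_dist = tail(x$trace$max_dup_dist, 1),
         convergence_iteration = as.integer(cut),
         converged = isTRUE(attr(cut, "converged")))
}

#' Diagnostic plot of a training run
#'
#' Mean negative-sampling loss, the span (min/max) of pairwise document
#' cosine distances and the maximum duplicate-pair distance per checkpoint.
#'
#' @param object A `tree2vec` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tree2vec
#' @export
autoplot.tree2vec <- function(object, ...) {
  tr <- object$trace %>%
    tidyr::pivot_longer(c("loss", "min_dist", "max_dist", "max_dup_dist"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "Embedding training diagnostics")
}

#' Write the embedding TSV and trace CSV of a model
#'
#' @param model A `tree2vec` object.
#' @param dir Output directory (created if needed). Writes `embeddings.tsv`
#'   (`tree_id` plus one column per dimension, primary trees only),
#'   `documents_embeddings.tsv` (all documents incl. duplicates/anchors) and
#'   `trace.csv`.
#' @return `dir`, invisibly.
#' @export
write_embeddings <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pm <- primary_vectors(model)
  colnames(pm) <- paste0("v", seq_len(ncol(pm)))
  readr::write_tsv(bind_cols(tibble(tree_id = rownames(pm)), as_tibble(pm)),
                   file.path(dir, "embeddings.tsv"))
  am <- model$doc_vectors
  colnames(am) <- paste0("v", seq_len(ncol(am)))
  readr::write_tsv(bind_cols(tibble(doc_id = rownames(am)), as_tibble(am)),
                   file.path(dir, "documents_embeddings.tsv"))
  readr::write_csv(model$trace, file.path(dir, "trace.csv"))
  invisible(dir)
}
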