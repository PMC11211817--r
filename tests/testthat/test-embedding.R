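# Small corpora used across the trainer tests.
toy_documents <- function() {
  dplyr::bind_rows(
    tibble::tibble(tree_id = "d1", category = "NODE",
                   token = c("a", "b", "c", "d", "e"), count = 1L),
    tibble::tibble(tree_id = "d2", category = "NODE",
                   token = c("a", "b", "c", "d", "e"), count = 1L),
    tibble::tibble(tree_id = "d3", category = "NODE",
                   token = c("a", "x", "y", "z", "w"), count = 1L)
  )
}

test_that("training corpus doubles the cohort and adds disjoint anchors", {
  docs <- toy_documents()
  corpus <- prepare_training_corpus(docs, n_anchors = 1, seed = 1)
  expect_equal(nrow(corpus$origin), 2 * 3 + 1)
  expect_equal(sum(corpus$origin$role == "duplicate"), 3L)

  # N = 5 documents, one anchor -> 11 documents
  docs5 <- dplyr::bind_rows(lapply(1:5, function(i) {
    tibble::tibble(tree_id = paste0("t", i), category = "NODE",
                   token = c("a", paste0("w", i)), count = 1L)
  }))
  expect_equal(nrow(prepare_training_corpus(docs5, seed = 1)$origin), 11L)

  # N = 1 -> primary + duplicate + anchor
  expect_equal(nrow(prepare_training_corpus(docs5[docs5$tree_id == "t1", ],
                                            seed = 1)$origin), 3L)

  # anchor words never intersect any tree document
  anchor_words <- corpus$vocab$word[corpus$vocab$category == "ANCHOR"]
  tree_words <- corpus$vocab$word[corpus$vocab$category != "ANCHOR"]
  expect_length(intersect(anchor_words, tree_words), 0L)
  # duplicates copy word multisets verbatim
  expect_identical(corpus$doc_words[[1]], corpus$doc_words[[4]])
})

test_that("full-softmax likelihood matches closed forms and a brute-force oracle", {
  docs <- toy_documents()
  corpus <- prepare_training_corpus(docs, seed = 1)
  V <- nrow(corpus$vocab)
  L <- sum(lengths(corpus$doc_words))
  dim <- 8L
  zero <- list(doc_vectors = matrix(0, nrow(corpus$origin), dim),
               word_vectors = matrix(0, V, dim))
  expect_equal(softmax_log_likelihood(corpus, zero), L * log(1 / V))

  # |V| = 1: probability 1 for the only word, whatever the embeddings
  one_doc <- tibble::tibble(tree_id = "d", category = "NODE", token = "only",
                            count = 2L)
  corpus1 <- prepare_training_corpus(one_doc, seed = 1)
  corpus1$vocab <- corpus1$vocab[corpus1$vocab$category != "ANCHOR", , drop = FALSE]
  corpus1$vocab$word_index <- 1L
  corpus1$doc_words <- list(c(1L, 1L), c(1L, 1L))
  corpus1$origin <- corpus1$origin[1:2, ]
  v1 <- list(doc_vectors = matrix(rnorm(2 * 4), 2, 4),
             word_vectors = matrix(rnorm(4), 1, 4))
  expect_equal(softmax_log_likelihood(corpus1, v1), 0)

  # random embeddings against an independent term-by-term evaluation
  set.seed(42)
  emb <- list(doc_vectors = matrix(rnorm(nrow(corpus$origin) * dim, sd = 0.3),
                                   nrow(corpus$origin), dim),
              word_vectors = matrix(rnorm(V * dim, sd = 0.3), V, dim))
  oracle <- 0
  for (d in seq_along(corpus$doc_words)) {
    for (w in corpus$doc_words[[d]]) {
      num <- exp(sum(emb$doc_vectors[d, ] * emb$word_vectors[w, ]))
      den <- sum(exp(as.numeric(emb$word_vectors %*% emb$doc_vectors[d, ])))
      oracle <- oracle + log(num / den)
    }
  }
  expect_equal(softmax_log_likelihood(corpus, emb), oracle, tolerance = 1e-10)
})

test_that("training is bitwise deterministic given the seed", {
  docs <- toy_documents()
  corpus <- prepare_training_corpus(docs, seed = 9)
  p <- train_params(dim = 8, iterations = 40, seed = 9)
  m1 <- train_embeddings(corpus, p)
  m2 <- train_embeddings(corpus, p)
  expect_identical(m1$doc_vectors, m2$doc_vectors)
  expect_identical(m1$word_vectors, m2$word_vectors)
  m3 <- train_embeddings(corpus, train_params(dim = 8, iterations = 40, seed = 10))
  expect_false(identical(m1$doc_vectors, m3$doc_vectors))
})

test_that("duplicates converge to near-zero distance and sharing orders distances", {
  docs <- toy_documents()
  corpus <- prepare_training_corpus(docs, seed = 2)
  model <- train_embeddings(corpus, train_params(dim = 8, iterations = 300, seed = 2))
  expect_lt(tail(model$trace$max_dup_dist, 1), 0.05)

  # d1/d2 share 5 words, d1/d3 share 1: distance(d1,d2) < distance(d1,d3)
  # holds for a clear majority of seeds
  wins <- 0L
  for (s in 1:10) {
    corp <- prepare_training_corpus(docs, seed = s)
    m <- train_embeddings(corp, train_params(dim = 8, iterations = 200, seed = s))
    D <- cosine_distance_matrix(m)
    wins <- wins + (D["d1", "d2"] < D["d1", "d3"])
  }
  expect_gte(wins, 9L)
})

test_that("a tree sharing nothing stays farther than any duplicate pair", {
  docs <- dplyr::bind_rows(
    toy_documents(),
    tibble::tibble(tree_id = "loner", category = "NODE",
                   token = paste0("q", 1:5), count = 1L)
  )
  corpus <- prepare_training_corpus(docs, seed = 4)
  model <- train_embeddings(corpus, train_params(dim = 8, iterations = 300, seed = 4))
  D <- cosine_distance_matrix(model)
  dup_max <- tail(model$trace$max_dup_dist, 1)
  expect_gt(min(D["loner", c("d1", "d2", "d3")]), dup_max)
})

test_that("negative-sampling training climbs the exact softmax objective", {
  docs <- toy_documents()
  corpus <- prepare_training_corpus(docs, seed = 5)
  p_early <- train_params(dim = 8, iterations = 5, seed = 5)
  p_late <- train_params(dim = 8, iterations = 200, seed = 5)
  ll_early <- softmax_log_likelihood(corpus, train_embeddings(corpus, p_early))
  ll_late <- softmax_log_likelihood(corpus, train_embeddings(corpus, p_late))
  expect_gt(ll_late, ll_early)
})

test_that("convergence cutoff applies the steadiness and duplicate rules", {
  flat <- tibble::tibble(iteration = seq(10, 100, 10), loss = 1,
                         min_dist = 0, max_dist = 1, max_dup_dist = 0)
  cut <- convergence_cutoff(flat, patience = 3, tol = 1e-3)
  expect_equal(as.integer(cut), 40L)  # first checkpoint with 3 flat steps behind it
  expect_true(attr(cut, "converged"))

  # loss flattens at checkpoint 7 of 10
  falling <- flat
  falling$loss <- c(10, 8, 6, 4, 2, 1.2, 1.001, 1.0008, 1.0007, 1.0007)
  cut2 <- convergence_cutoff(falling, patience = 2, tol = 1e-3)
  expect_equal(as.integer(cut2), 90L)

  # duplicates never converge -> last checkpoint, flagged and warned
  stuck <- flat
  stuck$max_dup_dist <- 0.5
  expect_warning(cut3 <- convergence_cutoff(stuck, patience = 3), "never")
  expect_equal(as.integer(cut3), 100L)
  expect_false(attr(cut3, "converged"))
})

test_that("tidy and glance expose the fitted embedding", {
  docs <- toy_documents()
  corpus <- prepare_training_corpus(docs, seed = 1)
  model <- train_embeddings(corpus, train_params(dim = 8, iterations = 30, seed = 1))
  td <- generics::tidy(model)
  expect_equal(nrow(td), 7L)
  expect_true(all(c("doc_id", "tree_id", "role", "e1", "e8") %in% names(td)))
  gl <- generics::glance(model)
  expect_equal(gl$n_trees, 3L)
  expect_equal(gl$dim, 8L)
})
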