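block_matrix <- function(sizes, within = 0, between = 1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  d <- matrix(between, n, n)
  for (g in seq_along(sizes)) d[lab == g, lab == g] <- within
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  d
}

test_that("cosine distances are clamped to [0, 1] with a zero diagonal", {
  m <- rbind(a = c(1, 0), b = c(2, 0), c = c(0, 3), d = c(-1, 0))
  D <- cosine_distance_matrix(m)
  expect_equal(unname(D["a", "b"]), 0)          # identical direction
  expect_equal(unname(D["a", "c"]), 1)          # orthogonal
  expect_equal(unname(D["a", "d"]), 1)          # antipodal, clamped from 2
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_true(isSymmetric(unclass(D)))

  expect_error(cosine_distance_matrix(rbind(a = c(0, 0), b = c(1, 0))),
               "zero-norm.*'a'")
})

test_that("distance matrices from trained models satisfy their invariants", {
  docs <- dplyr::bind_rows(lapply(1:4, function(i) {
    tibble::tibble(tree_id = paste0("t", i), category = "NODE",
                   token = c("shared", paste0("w", i, "_", 1:3)), count = 1L)
  }))
  corpus <- prepare_training_corpus(docs, seed = 3)
  model <- train_embeddings(corpus, train_params(dim = 8, iterations = 50, seed = 3))
  D <- cosine_distance_matrix(model)
  expect_equal(rownames(D), paste0("t", 1:4))  # duplicates and anchors excluded
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(unname(diag(D)), rep(0, 4))
})

test_that("the dendrogram is cut at the coarsest clustering within the threshold", {
  # two perfect blocks
  cl <- hierarchical_clusters(block_matrix(c(3, 3)), 0.4)
  expect_equal(cl$k, 2L)
  expect_equal(cl$silhouette, 1)

  # all distances below the threshold: one cluster, silhouette undefined
  cl1 <- hierarchical_clusters(block_matrix(c(6), within = 0.1, between = 0.1), 0.4)
  expect_equal(cl1$k, 1L)
  expect_true(is.na(cl1$silhouette))

  # 3 points, d(1,2) = 0.2, d(1,3) = d(2,3) = 0.9: only {1,2},{3} satisfies
  # the max-intra rule at threshold 0.4 (exhaustive over partitions)
  d3 <- matrix(c(0, .2, .9, .2, 0, .9, .9, .9, 0), 3, 3,
               dimnames = list(paste0("t", 1:3), paste0("t", 1:3)))
  cl3 <- hierarchical_clusters(d3, 0.4)
  a <- cl3$assignments
  expect_equal(a$cluster[a$tree_id == "t1"], a$cluster[a$tree_id == "t2"])
  expect_false(a$cluster[a$tree_id == "t3"] == a$cluster[a$tree_id == "t1"])
})

test_that("raising the threshold never increases the number of clusters", {
  set.seed(7)
  for (rep in 1:4) {
    m <- matrix(rnorm(15 * 6), 15, 6)
    rownames(m) <- paste0("t", 1:15)
    D <- cosine_distance_matrix(m)
    ks <- vapply(seq(0.05, 1, by = 0.05),
                 function(th) hierarchical_clusters(D, th)$k, numeric(1))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("silhouette matches a direct a(i)/b(i) recomputation", {
  expect_equal(silhouette_score(block_matrix(c(4, 4)),
                                rep(1:2, each = 4)), 1)

  silhouette_oracle <- function(d, cl) {
    n <- nrow(d)
    mean(vapply(seq_len(n), function(i) {
      own <- which(cl == cl[i] & seq_len(n) != i)
      if (!length(own)) return(0)
      a <- mean(d[i, own])
      b <- min(vapply(setdiff(unique(cl), cl[i]),
                      function(g) mean(d[i, cl == g]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1)))
  }
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    d <- matrix(runif(n * n), n, n)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
    cl <- sample(1:3, n, replace = TRUE)
    cl[1:3] <- 1:3  # ensure all clusters non-empty
    expect_equal(silhouette_score(d, cl), silhouette_oracle(d, cl),
                 tolerance = 1e-12)
  }

  expect_error(silhouette_score(block_matrix(c(4)), rep(1, 4)),
               class = "oncotreevec_single_cluster")
})

test_that("parameter recommendation ranks configurations by silhouette", {
  # two label groups on one common chain structure: the group signal lives
  # only in the node labels. A structure-only vocabulary sees all trees as
  # identical (one cluster, silhouette undefined, ranked last); a nodes-only
  # vocabulary separates the groups cleanly and ranks first.
  cohort <- dplyr::bind_rows(lapply(1:8, function(i) {
    g <- if (i <= 4) "a" else "b"
    chain_tree(sprintf("t%d", i),
               c(sprintf("%s_c%02d", g, 1:4),            # group-shared labels
                 sprintf("%s_t%d_u%02d", g, i, 1:4)))    # tree-unique labels
  }))
  nodes_only <- c(NEIGHBORHOOD = 0L, ROOT_CHILD = 0L, DIRECT_EDGE = 0L,
                  PATH_PAIR = 0L, EXCLUSIVE_PAIR = 0L, STRUCTURE = 0L)
  structure_only <- c(NODE = 0L, NEIGHBORHOOD = 0L, ROOT_CHILD = 0L,
                      DIRECT_EDGE = 0L, PATH_PAIR = 0L, EXCLUSIVE_PAIR = 0L)
  grid <- tibble::tibble(
    wl_max_k = c(0L, 3L),
    dim = c(16L, 16L),
    augment = list(nodes_only, structure_only),
    filter_override = list(c(NODE = FALSE), NULL)
  )
  ranked <- suppressWarnings(recommend_parameters(
    cohort, grid, params = train_params(iterations = 150), seed = 2))
  expect_equal(nrow(ranked), 2L)
  expect_equal(ranked$wl_max_k[1], 0L)  # nodes-only configuration wins
  expect_true(ranked$single_cluster[2])  # undefined silhouette ranks last

  # singleton grid returns that configuration with its silhouette
  one <- suppressWarnings(recommend_parameters(
    cohort, grid[1, ], params = train_params(iterations = 100), seed = 2))
  expect_equal(nrow(one), 1L)
  expect_true(is.numeric(one$silhouette))

  # equal silhouettes break ties by smaller dimension
  g2 <- tibble::tibble(wl_max_k = c(0L, 0L), dim = c(32L, 16L),
                       augment = list(nodes_only, nodes_only),
                       filter_override = list(c(NODE = FALSE), c(NODE = FALSE)))
  r2 <- suppressWarnings(recommend_parameters(
    cohort, g2, params = train_params(iterations = 60), seed = 2))
  if (!anyNA(r2$silhouette) && abs(diff(r2$silhouette)) < 1e-9) {
    expect_equal(r2$dim[1], 16L)
  }
})

test_that("dominant words report per-cluster containment fractions", {
  docs <- dplyr::bind_rows(
    tibble::tibble(tree_id = "t1", category = "NODE", token = c("a", "b"), count = 1L),
    tibble::tibble(tree_id = "t2", category = "NODE", token = c("a", "c"), count = 1L),
    tibble::tibble(tree_id = "t3", category = "NODE", token = "z", count = 1L),
    tibble::tibble(tree_id = "t4", category = "NODE", token = "z", count = 1L)
  )
  cl <- tibble::tibble(tree_id = paste0("t", 1:4), cluster = c(1L, 1L, 2L, 2L))
  dw <- dominant_words(cl, docs, min_fraction = 0)
  c1 <- dw[dw$cluster == 1, ]
  expect_equal(c1$token[1], "a")
  expect_equal(c1$fraction[c1$token == "a"], 1)
  expect_equal(c1$fraction[c1$token == "b"], 0.5)
  expect_equal(dw$fraction[dw$cluster == 2 & dw$token == "z"], 1)
})

test_that("autoplot methods return ggplot objects", {
  set.seed(2)
  m <- matrix(rnorm(8 * 4), 8, 4)
  rownames(m) <- paste0("t", 1:8)
  D <- cosine_distance_matrix(m)
  expect_s3_class(ggplot2::autoplot(D), "ggplot")

  docs <- dplyr::bind_rows(lapply(1:3, function(i) {
    tibble::tibble(tree_id = paste0("t", i), category = "NODE",
                   token = c("a", paste0("u", i)), count = 1L)
  }))
  corpus <- prepare_training_corpus(docs, seed = 1)
  model <- train_embeddings(corpus, train_params(dim = 4, iterations = 20, seed = 1))
  expect_s3_class(ggplot2::autoplot(model), "ggplot")
})
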