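test_that("WL tokens encode depth-k labeled subtrees, invariant to child order", {
  # single node: token encodes (label, no children)
  lone <- make_tree("s", list())
  expect_equal(wl_relabel(lone, 1)$token, "ROOT()")

  # chains ROOT->A->B vs ROOT->A->C: iteration-2 tokens of A differ
  ab <- chain_tree("ab", c("A", "B"))
  ac <- chain_tree("ac", c("A", "C"))
  tok <- function(tr, node, k) {
    w <- wl_relabel(tr, k)
    w$token[w$node_id == node & w$iteration == k]
  }
  expect_false(tok(ab, 1L, 2L) == tok(ac, 1L, 2L))

  # permuting children yields identical token multisets (property)
  t1 <- make_tree("p1", list(c("ROOT", "A"), c("A", "B"), c("A", "C"), c("B", "D")))
  t2 <- make_tree("p2", list(c("ROOT", "A"), c("A", "C"), c("A", "B"), c("B", "D")))
  for (k in 1:3) {
    expect_setequal(wl_relabel(t1, k)$token, wl_relabel(t2, k)$token)
  }
})

test_that("WL tokens agree with an exhaustive canonical-form oracle", {
  # two nodes in different random trees get equal iteration-k tokens exactly
  # when their depth-k subtrees are isomorphic (canonical serialization)
  for (seed in 1:6) {
    tr1 <- random_test_tree(sample(3:8, 1), seed = seed, tree_id = "o1")
    tr2 <- random_test_tree(sample(3:8, 1), seed = seed + 100, tree_id = "o2")
    for (k in 1:2) {
      w1 <- wl_relabel(tr1, k, use_labels = FALSE)
      w2 <- wl_relabel(tr2, k, use_labels = FALSE)
      for (v1 in tr1$node_id) {
        for (v2 in tr2$node_id) {
          same_wl <- w1$token[w1$node_id == v1 & w1$iteration == k] ==
            w2$token[w2$node_id == v2 & w2$iteration == k]
          same_oracle <- canonical_subtree(tr1, v1, k, use_labels = FALSE) ==
            canonical_subtree(tr2, v2, k, use_labels = FALSE)
          expect_equal(same_wl, same_oracle)
        }
      }
    }
  }
})

test_that("pair relations enumerate lineage and exclusivity words", {
  # root with children A, B; A -> C
  t <- make_tree("pr", list(c("ROOT", "A"), c("ROOT", "B"), c("A", "C")))
  pr <- extract_pair_relations(t)
  get <- function(cat) sort(pr$token[pr$category == cat])
  expect_equal(get("ROOT_CHILD"), c("root>A", "root>B"))
  expect_equal(get("DIRECT_EDGE"), "A>C")
  expect_equal(get("PATH_PAIR"), character(0))
  expect_equal(get("EXCLUSIVE_PAIR"), c("A||B", "B||C"))

  # linear chain: no exclusivity, one path pair
  ch <- chain_tree("ch", c("A", "B", "C"))
  pr2 <- extract_pair_relations(ch)
  expect_equal(pr2$token[pr2$category == "PATH_PAIR"], "A>>C")
  expect_equal(sum(pr2$category == "EXCLUSIVE_PAIR"), 0L)

  # single-node tree: all four sets empty
  expect_equal(nrow(extract_pair_relations(make_tree("s", list()))), 0L)
})

test_that("every mutation pair is exactly one of direct/path/exclusive", {
  for (seed in 1:8) {
    n <- sample(3:12, 1)
    tr <- random_test_tree(n, seed = seed)
    pr <- extract_pair_relations(tr)
    n_pairs <- sum(pr$category %in% c("DIRECT_EDGE", "PATH_PAIR", "EXCLUSIVE_PAIR"))
    expect_equal(n_pairs, choose(n - 1, 2))
  }
})

test_that("document extraction matches the closed-form word counts", {
  # chain ROOT->A->B with wl 0 and structure off: NODE + pair words only
  ch <- chain_tree("d", c("A", "B"))
  doc <- extract_document(ch, vocab_config(wl_max_k = 0, augment = c(STRUCTURE = 0)))
  expect_setequal(paste(doc$category, doc$token),
                  c("NODE A", "NODE B", "ROOT_CHILD root>A", "DIRECT_EDGE A>B"))

  # NODE + NEIGHBORHOOD word count is n * (K + 1) for n mutations
  for (seed in 1:5) {
    n <- sample(2:10, 1)
    K <- sample(1:3, 1)
    tr <- random_test_tree(n + 1, seed = seed)  # n mutations + root
    doc <- extract_document(tr, vocab_config(wl_max_k = K))
    n_nn <- sum(doc$count[doc$category == "NODE" |
                            startsWith(doc$category, "NEIGHBORHOOD")])
    expect_equal(n_nn, n * (K + 1))
  }

  # single-node tree: only structure words (if enabled), else empty
  lone <- make_tree("s", list())
  doc_s <- extract_document(lone, vocab_config())
  expect_true(all(startsWith(doc_s$category, "STRUCTURE")))
  doc_e <- extract_document(lone, vocab_config(augment = c(STRUCTURE = 0)))
  expect_equal(nrow(doc_e), 0L)
})

test_that("corpus filtering drops cohort-unique words and augmentation scales counts", {
  cohort <- dplyr::bind_rows(
    make_tree("t1", list(c("ROOT", "A"), c("A", "B"))),
    make_tree("t2", list(c("ROOT", "B"), c("B", "C")))
  )
  cfg <- vocab_config(wl_max_k = 0, augment = c(STRUCTURE = 0, ROOT_CHILD = 0,
                                                DIRECT_EDGE = 0, PATH_PAIR = 0,
                                                EXCLUSIVE_PAIR = 0))
  # NODE sets {A,B} and {B,C} -> only B survives in both documents
  out <- build_corpus(cohort, cfg)
  expect_equal(out$token[out$tree_id == "t1"], "B")
  expect_equal(out$token[out$tree_id == "t2"], "B")

  # filter off: documents equal raw extraction
  cfg_off <- vocab_config(wl_max_k = 0,
                          augment = c(STRUCTURE = 0, ROOT_CHILD = 0,
                                      DIRECT_EDGE = 0, PATH_PAIR = 0,
                                      EXCLUSIVE_PAIR = 0),
                          filter_unique = FALSE)
  out_off <- build_corpus(cohort, cfg_off)
  expect_setequal(out_off$token[out_off$tree_id == "t1"], c("A", "B"))

  # 2x augmentation doubles surviving counts of that category
  cohort2 <- dplyr::bind_rows(
    make_tree("t1", list(c("ROOT", "A"), c("A", "B"))),
    make_tree("t2", list(c("ROOT", "A"), c("A", "C")))
  )
  cfg_aug <- vocab_config(wl_max_k = 0, augment = c(STRUCTURE = 0, ROOT_CHILD = 2))
  out2 <- build_corpus(cohort2, cfg_aug)
  rc <- out2[out2$category == "ROOT_CHILD" & out2$tree_id == "t1", ]
  expect_equal(rc$count, 2L)
})

test_that("an all-unique tree keeps an empty document, with a warning", {
  cohort <- dplyr::bind_rows(
    make_tree("t1", list(c("ROOT", "A"), c("A", "B"))),
    make_tree("t2", list(c("ROOT", "A"), c("A", "C"))),
    make_tree("lonely", list(c("ROOT", "X"), c("X", "Y")))
  )
  cfg <- vocab_config(wl_max_k = 0, augment = c(STRUCTURE = 0, EXCLUSIVE_PAIR = 0,
                                                PATH_PAIR = 0))
  expect_warning(out <- build_corpus(cohort, cfg), "empty document")
  expect_false("lonely" %in% out$tree_id)
})

test_that("document intersections equal brute-force subtree enumeration", {
  # vocabulary-intersection symmetry against the exhaustive oracle on small trees
  cfg <- vocab_config(wl_max_k = 3, structure_wl_max_k = 3, filter_unique = FALSE)
  for (seed in 1:5) {
    a <- random_test_tree(sample(3:8, 1), seed = seed, tree_id = "ta")
    b_labels <- sprintf("ta_m%02d", 1:8)  # same label pool -> real overlap
    b <- oncotreevec::random_tree(sample(3:8, 1), label_pool = b_labels,
                                  seed = seed + 50, tree_id = "tb")
    doc_a <- extract_document(a, cfg)
    doc_b <- extract_document(b, cfg)
    pkg_inter <- length(intersect(paste(doc_a$category, doc_a$token),
                                  paste(doc_b$category, doc_b$token)))
    oracle_inter <- length(intersect(unique(brute_force_words(a)),
                                     unique(brute_force_words(b))))
    expect_equal(pkg_inter, oracle_inter)
  }
})

test_that("vocabulary dump writes the documented TSV layout", {
  doc <- extract_document(chain_tree("d", c("A", "B")), vocab_config())
  f <- file.path(withr::local_tempdir(), "vocab.tsv")
  dump_vocabulary(doc, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(names(back), c("tree_id", "category", "token", "count"))
  expect_equal(nrow(back), nrow(doc))
})

test_that("undirected WL aggregation also sees the parent", {
  ch <- chain_tree("u", c("A", "B", "C"))
  directed <- wl_relabel(ch, 1)
  undirected <- wl_relabel(ch, 1, undirected = TRUE)
  # for the middle node B the directed token lists only child C, the
  # undirected one lists both neighbors A and C
  tok <- function(w) w$token[w$node_id == 2L]
  expect_equal(tok(directed), "B(C)")
  expect_equal(tok(undirected), "B(A,C)")
})
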