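---
title: "Embedding and clustering tumor mutation trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding and clustering tumor mutation trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

A tumor mutation tree is a rooted tree whose root stands for the germline
(neutral) cell population and whose other nodes are genomic events (point
mutations), ordered by the clonal lineage in which the tumor acquired them.
Cohorts of such trees carry more signal than flat mutation profiles: two
patients may share not just mutations but the *order* and *branch
arrangement* in which they occurred. This package clusters mutation-tree
cohorts by learning a fixed-length vector per tree such that trees sharing
evolutionary patterns are close in cosine space.

The method treats each tree as a *document* over a vocabulary of
category-tagged *words*, then fits a PV-DBOW (distributed bag of words)
document-embedding model with negative sampling. A document's words are:

* `NODE` — each mutation label on its own (a neighborhood of size 0);
* `NEIGHBORHOOD_k` — Weisfeiler-Lehman (WL) relabelings of the rooted,
  descendant-directed subtree of depth *k* below each mutation, for
  *k* = 1..`wl_max_k`. Two nodes in different trees receive the same token
  exactly when their labeled depth-*k* subtrees are isomorphic;
* `ROOT_CHILD` — `root>X` for each child of the root. The root's own label
  is dropped from the token so "tumors initiated by mutation X" match across
  cohorts;
* `DIRECT_EDGE` (`X>Y`), `PATH_PAIR` (`X>>Y`) — direct and indirect clonal
  co-occurrence: Y arises in the lineage of X, adjacent or at path distance
  at least 2;
* `EXCLUSIVE_PAIR` (`X||Y`, unordered) — clonal exclusivity: the two
  mutations sit on different branches and never share a lineage;
* `STRUCTURE_k` — WL tokens of the label-stripped tree (root included), so
  purely topological patterns (linear, branching, punctuated shapes) can
  match even when no label does.

Every unordered pair of distinct mutations falls in exactly one of
`DIRECT_EDGE`, `PATH_PAIR`, `EXCLUSIVE_PAIR`; the three categories partition
the `choose(n-1, 2)` pairs.

The embedding objective is the standard one: the probability of word *w* in
document *d* is a softmax over the whole vocabulary of `emb(d) . emb(w)`,
and training maximizes the summed log likelihood over all word occurrences.
The trainer approximates this with negative sampling — each sampled
(document, word) positive is contrasted against `negative` words drawn from
the unigram distribution raised to 3/4 — which is the classical
word2vec/doc2vec estimator for exactly this objective. The exact softmax
likelihood is kept in the package (`softmax_log_likelihood()`) purely as a
test oracle on small corpora; the test suite checks that negative-sampling
training increases it.

Two kinds of control documents calibrate the embedding space during
training (`prepare_training_corpus()`): a verbatim *duplicate* of every
document, expected to land at cosine distance 0 of its original, and at
least one *anchor* of entirely fresh words, expected to match nothing.
Duplicates double as the main convergence diagnostic; anchors pin the
"similarity 0" end of the scale. Both are dropped from every user-facing
distance matrix and clustering.

## Unique-word filtering and augmentation

A word that occurs in only one tree of the cohort cannot pull any two trees
together; it only dilutes the gradient signal of the words that do match.
`build_corpus()` therefore drops words with cohort document-frequency 1 by
default. The filter can be lifted per category (`filter_override`): keeping
unique `NODE`/`NEIGHBORHOOD` words while filtering the pairwise-relation
categories reproduces the regime in which each tree also "owns" its private
mutations, which attenuates similarity scores — both regimes are used by
the benchmarks below.

Per-category integer augmentation weights multiply the surviving counts.
Neighborhood words are intrinsically overrepresented — a tree with *n*
mutations contributes `n * (wl_max_k + 1)` `NODE`+`NEIGHBORHOOD` words —
while a tree rarely has more than a handful of surviving pairwise-relation
words, so weighting (e.g. `ROOT_CHILD = 2`) is how an analysis says which
patterns should dominate the matching. Weight 0 disables a category.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `wl_max_k` | 3 | largest labeled WL depth; beyond 3, fully matching labeled subtrees essentially never occur in real cohorts |
| `structure_wl_max_k` | 3 | largest label-free WL depth (size >= 1: single unlabeled nodes carry no information) |
| `augment` | 1 per category | per-category count multiplier, 0 disables |
| `filter_unique` | TRUE | drop cohort-unique words (per-category override available) |
| `dim` | 128, or 32 below 100 trees | embedding dimension; small cohorts spread too thinly at 128 |
| `iterations` | 500 | training passes; each document contributes up to `words_per_iter` sampled positions per pass |
| `alpha`, `alpha_min` | 0.025, 1e-4 | linear learning-rate decay (word2vec convention) |
| `decay_fraction` | 0.7 | fraction of training over which the decay runs; the tail trains at the floor |
| `negative` | 10 | negative samples per positive |
| `threshold` | 0.4 | clustering cutoff on cosine distance (0 = identical) |
| `n_anchors` | 1 | injected non-matching documents |

## Numerical and design choices

**Cosine distance is clamped to [0, 1].** Raw cosine distance ranges to 2;
anti-correlated embeddings are reported as "maximally dissimilar" (1) rather
than rescaling, which would shrink the informative [0, 1] range. Distances
are reported on this scale everywhere, including the 0.4 cluster cutoff.

**Cluster cut search.** Ward linkage (`ward.D2`) is applied to the cosine
distance matrix — a pragmatic and common choice even though cosine distances
are not Euclidean; average linkage is available. The flat clustering is the
*coarsest* cut of the dendrogram in which every cluster's maximum pairwise
original distance is at most the threshold, found by scanning cut sizes
k = 1, 2, ... and stopping at the first that satisfies the constraint. All
singletons always satisfy it, so the search cannot fail, and raising the
threshold can only stop the scan earlier — the cluster count is monotone in
the threshold. Silhouettes use the precomputed distance matrix; an
all-singleton clustering scores 0 and a single cluster has no silhouette
(signaled as a classed condition, not a number).

**Position sampling in the trainer.** Each iteration visits every document
and samples up to `words_per_iter` positions uniformly from its expanded
word multiset. Sequential sweeps over the count-sorted multiset were
observed to leave duplicate pairs stuck in distinct saturated attractors
(correlated bursts of identical updates saturate the logistic losses before
the noise can average out); uniform sampling removes the artifact. The
learning-rate floor from `decay_fraction` onward gives duplicate pairs a
long low-noise tail in which to contract to their expected distance 0.

**Empty documents.** Unique-word filtering can empty a document (a tree
sharing nothing with the cohort). Such trees are kept — they embed at their
random initialization and land far from everything, which is the correct
reading of "matches nothing" — but their duplicate pairs are excluded from
the duplicate-distance diagnostic, since an unupdated vector pair cannot
converge and would make the diagnostic meaningless.

**Convergence cutoff.** `convergence_cutoff()` returns the earliest
checkpoint at which the relative loss change stayed below `tol = 1e-3` for
`patience = 5` consecutive checkpoints *and* the maximum duplicate distance
is below 0.05. On stochastic traces the loss estimate itself is sampled, so
the rule may never fire; the fallback is the last checkpoint with a warning
and `converged = FALSE`.

**Root handling.** Whatever the input calls its root, it is renamed to the
sentinel `ROOT` at parse time: the root is the germline, not a mutation.
The root is excluded from `NODE`, `NEIGHBORHOOD` centers and all mutation
pairs; it participates only in `ROOT_CHILD` (label dropped) and in
`STRUCTURE` words. WL aggregation runs over children only — mutation order
is directional — with an undirected option (`wl_undirected`) for
compatibility with whole-graph embedding tools that ignore direction.

**Event-set labels.** For trees whose nodes carry sets of events
(semicolon-joined), `jaccard_relabel()` merges all labels within a connected
component of the "Jaccard distance <= threshold" graph (single linkage, so
chained near-matches share one label) onto the lexicographically smallest
member set. The operation is idempotent because component representatives
are themselves member sets.

## The synthetic benchmarks

Three generators regenerate the benchmark cohorts from their published
construction rules; exact trees are not public, so reproduction of the
statistics is statistical rather than bitwise.

**Benchmark I** (`simulate_dataset1()`): 16 groups; each group starts from a
random-attachment tree with a fresh label set, group size = number of
mutations, drawn uniformly from 9–34. Tree at rank *k* keeps the start
labels on the `size - k` nodes closest (undirected BFS) to a fixed center
node and fresh labels elsewhere, so vocabulary intersections with the start
tree decrease strictly with rank. Vocabulary: nodes, neighborhoods and
structures (pair categories off, as the group signal is label/structure
matching). Statistics: the mean silhouette of the 0.4-cut clustering over
10 training seeds, and the mean one-sided rank deviation — for each tree at
rank r >= 2, `max(0, sim - min(sim of rank r-1))` against the start tree,
averaged within then across groups. Violations are one-sided because an
ordering that is *more* separated than designed is not an error.

**Benchmark II** (`simulate_dataset2()`): deterministic. A reference chain
of 50 uniquely labeled mutations and 51 derived chains T_m keeping the
first m reference labels, so any two documents intersect in exactly
`min(a, b)` node words. Vocabulary: node labels only, *not* uniqueness
filtered — with filtering, T_0's document would be empty, its duplicate
could never reach distance 0, and its distances would sit at
random-initialization spread, contradicting both diagnostics the ladder is
meant to exercise. Statistics: the mean per-tree rank deviation (every tree
in turn as reference, others ranked by designed match count, ties sharing a
rank) and the antidiagonal consistency — pairs grouped by designed match
count, population standard deviation of distances within each group
(singletons contribute 0), averaged over groups. Population rather than
sample deviation because each group is the complete set of pairs at that
count, not a sample; the per-group table also reports the sample version.

**Benchmark III** (`simulate_dataset3()`): 13 fixed pairs of trees — one
sharing a size-1 neighborhood (a center with two children, which entails
two direct-edge words and one exclusivity word), one sharing a root-child
relation, three each sharing one path pair, one direct edge, one exclusive
pair, and two non-matching pairs (same mutations in reverse order; same
mutations under different branching), padded with tree-unique labels. Two
vocabulary regimes are compared: WL size 0 uses the pairwise-relation
categories only with unique-word filtering, under which each matching
pair's filtered documents are exactly the shared pattern (near-perfect
recovery) and the non-matching pairs' documents are empty; WL size 1 adds
node and neighborhood words exempted from filtering, so every tree retains
its private labels and the separation is attenuated. The statistic is the
silhouette over all 26 trees with the 13 intended pairs as clusters, plus
the mean distance over all "negative" (cross-pair) tree pairs.

## Problem sizes used by the tests and the acceptance script

Benchmark I trains 800 iterations at dimension 32 with 64 sampled positions
per document per iteration and the rate floor from 60% of training; the ten runs
dominate the benchmark scripts' runtime (minutes on one core), with
duplicate distances near 0.01. Benchmark II trains the full 50-word documents for 200
iterations at dimension 128 (the ladder is a rank-ordering task, not a
clustering task, so the small-cohort dimension heuristic does not apply —
the larger space separates the 52 near-collinear documents more cleanly).
Benchmark III trains 600 iterations at dimension 32; the long floor phase
stabilizes the distances of the untrained (empty-document) trees'
counterparts. These sizes are the package's documented operating points for
the benchmarks; `dataset1_train_params()` and friends pin them so scripts
and tests agree.

## What the generators do and do not emulate

The generators produce exact match-count structure (who shares how many
words with whom) under fresh, collision-free label pools. Real cohorts
differ in ways the benchmarks deliberately ignore: mutation frequencies are
heavy-tailed rather than uniform, label sets overlap across unrelated
patients (hot-spot genes), trees are inferred with error and varying
resolution, and cohorts mix tree sizes and shapes far less cleanly than a
fixed-structure group. Passing benchmarks therefore demonstrates that the
pipeline recovers designed similarity structure of the kinds listed — not
that any particular real cohort will cluster as crisply.

## Known limitations

* Embeddings are cohort-specific: adding a tree changes the vocabulary and
  requires retraining. No online or transfer learning.
* Cosine similarity is not transitive, and trees are not exactly embeddable
  in a low-dimensional inner-product space; very large or deeply
  hierarchical pattern systems may not admit a clean flat clustering at any
  threshold.
* Word matching is exact. Near-miss subtrees (one label off) share only
  their smaller common words; there is no soft matching. For event-set
  nodes, `jaccard_relabel()` is the supported coarsening step.
* The silhouette-based parameter recommendation compares clusterings the
  cutoff produces; on cohorts without cluster structure (similarity
  ladders) it can prefer coarse, structure-dominated groupings — it is a
  screening tool, not a substitute for inspecting the heatmap and the
  dominant-word report.
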