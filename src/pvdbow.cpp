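#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Walker alias table for O(1) sampling from the unigram^0.75 noise distribution.
struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;
  int n;

  void build(const std::vector<double>& w) {
    n = (int)w.size();
    prob.assign(n, 0.0);
    alias.assign(n, 0);
    double total = 0.0;
    for (double x : w) total += x;
    std::vector<double> p(n);
    for (int i = 0; i < n; ++i) p[i] = w[i] * n / total;
    std::vector<int> small, large;
    for (int i = 0; i < n; ++i) (p[i] < 1.0 ? small : large).push_back(i);
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = p[s];
      alias[s] = l;
      p[l] = (p[l] + p[s]) - 1.0;
      (p[l] < 1.0 ? small : large).push_back(l);
    }
    for (int s : small) prob[s] = 1.0;
    for (int l : large) prob[l] = 1.0;
  }

  int sample(std::mt19937_64& rng, std::uniform_real_distribution<double>& u) {
    double x = u(rng) * n;
    int i = (int)x;
    if (i >= n) i = n - 1;
    return (x - i) < prob[i] ? i : alias[i];
  }
};

// Precomputed logistic table (word2vec style): sigmoid on [-MAX_EXP, MAX_EXP].
#define EXP_TABLE_SIZE 2048
#define MAX_EXP 8.0
static double exp_table[EXP_TABLE_SIZE];
static bool exp_table_ready = false;

static void build_exp_table() {
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    double x = (2.0 * i / EXP_TABLE_SIZE - 1.0) * MAX_EXP;
    exp_table[i] = 1.0 / (1.0 + std::exp(-x));
  }
  exp_table_ready = true;
}

static inline double sigmoid(double x) {
  if (x >= MAX_EXP) return 1.0;
  if (x <= -MAX_EXP) return 0.0;
  int i = (int)((x / MAX_EXP + 1.0) * (EXP_TABLE_SIZE / 2));
  return exp_table[i];
}

// Cosine distance between two rows, clamped to [0, 1].
static double cos_dist(const std::vector<double>& m, int dim, int a, int b) {
  const double* va = m.data() + (size_t)a * dim;
  const double* vb = m.data() + (size_t)b * dim;
  double dot = 0.0, na = 0.0, nb = 0.0;
  for (int i = 0; i < dim; ++i) {
    dot += va[i] * vb[i];
    na += va[i] * va[i];
    nb += vb[i] * vb[i];
  }
  double den = std::sqrt(na) * std::sqrt(nb);
  if (den <= 0.0) return 1.0;
  double d = 1.0 - dot / den;
  if (d < 0.0) d = 0.0;
  if (d > 1.0) d = 1.0;
  return d;
}

// PV-DBOW with negative sampling. `docs` holds 0-based word indices per
// document (counts expanded). One iteration = one pass over documents in
// which each document contributes min(L, words_per_iter) positive pairs,
// positions sampled uniformly from its multiset (sequential sweeps over the
// count-sorted multiset produce correlated update bursts that leave
// duplicate pairs in distinct saturated attractors). Deterministic for a
// fixed seed.
// [[Rcpp::export]]
List pvdbow_train_cpp(List docs, NumericVector noise_weights,
                      IntegerMatrix dup_pairs, int dim, int iterations,
                      double alpha0, double alpha_min, int negative,
                      double seed, int words_per_iter, int checkpoint_every,
                      double decay_fraction) {
  const int n_docs = docs.size();
  const int vocab = noise_weights.size();
  std::vector<std::vector<int>> D(n_docs);
  long long positions_per_iter = 0;
  for (int d = 0; d < n_docs; ++d) {
    IntegerVector v = docs[d];
    D[d].assign(v.begin(), v.end());
    int L = (int)D[d].size();
    int m = (words_per_iter > 0 && words_per_iter < L) ? words_per_iter : L;
    positions_per_iter += m;
  }
  if (vocab < 1) stop("empty vocabulary");

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif01(0.0, 1.0);

  std::vector<double> dv((size_t)n_docs * dim), wv((size_t)vocab * dim);
  const double r = 0.5 / dim;
  for (auto& x : dv) x = (unif01(rng) - 0.5) * 2.0 * r;
  for (auto& x : wv) x = (unif01(rng) - 0.5) * 2.0 * r;

  AliasTable noise;
  {
    std::vector<double> w(noise_weights.begin(), noise_weights.end());
    noise.build(w);
  }

  const long long total_steps = (long long)iterations * std::max(positions_per_iter, 1LL);
  const double decay_steps = std::max(1.0, total_steps * decay_fraction);
  long long step = 0;
  double loss_acc = 0.0;
  long long loss_n = 0;
  std::vector<double> neu1e(dim);

  std::vector<double> cp_iter, cp_loss, cp_min, cp_max, cp_dup;
  bool diverged = false;

  if (!exp_table_ready) build_exp_table();

  for (int iter = 1; iter <= iterations && !diverged; ++iter) {
    // exact log-loss is only accumulated on checkpoint iterations
    const bool track_loss = (iter % checkpoint_every == 0 || iter == iterations);
    for (int d = 0; d < n_docs; ++d) {
      const int L = (int)D[d].size();
      if (L == 0) continue;
      const int m = (words_per_iter > 0 && words_per_iter < L) ? words_per_iter : L;
      double* dvec = dv.data() + (size_t)d * dim;
      for (int s = 0; s < m; ++s) {
        int pos = (int)(unif01(rng) * L);
        if (pos >= L) pos = L - 1;
        const int target = D[d][pos];
        const double alpha = std::max(
            alpha_min, alpha0 - (alpha0 - alpha_min) * (step / decay_steps));
        std::fill(neu1e.begin(), neu1e.end(), 0.0);
        for (int k = 0; k <= negative; ++k) {
          int w;
          double label;
          if (k == 0) {
            w = target;
            label = 1.0;
          } else {
            w = noise.sample(rng, unif01);
            if (w == target) continue;
            label = 0.0;
          }
          double* wvec = wv.data() + (size_t)w * dim;
          double f = 0.0;
          for (int i = 0; i < dim; ++i) f += dvec[i] * wvec[i];
          const double p = sigmoid(f);
          const double g = (label - p) * alpha;
          if (track_loss) {
            loss_acc -= (label > 0.5) ? std::log(std::max(p, 1e-12))
                                      : std::log(std::max(1.0 - p, 1e-12));
            ++loss_n;
          }
          for (int i = 0; i < dim; ++i) {
            neu1e[i] += g * wvec[i];
            wvec[i] += g * dvec[i];
          }
        }
        for (int i = 0; i < dim; ++i) dvec[i] += neu1e[i];
        ++step;
      }
    }
    if (iter % checkpoint_every == 0 || iter == iterations) {
      double mn = 1.0, mx = 0.0;
      for (int a = 0; a < n_docs; ++a) {
        for (int b = a + 1; b < n_docs; ++b) {
          const double dd = cos_dist(dv, dim, a, b);
          if (dd < mn) mn = dd;
          if (dd > mx) mx = dd;
        }
      }
      double dup = 0.0;
      for (int j = 0; j < dup_pairs.nrow(); ++j) {
        const double dd = cos_dist(dv, dim, dup_pairs(j, 0) - 1, dup_pairs(j, 1) - 1);
        if (dd > dup) dup = dd;
      }
      const double mean_loss = loss_n > 0 ? loss_acc / loss_n : NA_REAL;
      cp_iter.push_back(iter);
      cp_loss.push_back(mean_loss);
      cp_min.push_back(n_docs > 1 ? mn : 0.0);
      cp_max.push_back(n_docs > 1 ? mx : 0.0);
      cp_dup.push_back(dup);
      loss_acc = 0.0;
      loss_n = 0;
      if (!std::isfinite(mean_loss)) diverged = true;
    }
  }

  NumericMatrix doc_out(n_docs, dim), word_out(vocab, dim);
  for (int d = 0; d < n_docs; ++d)
    for (int i = 0; i < dim; ++i) doc_out(d, i) = dv[(size_t)d * dim + i];
  for (int w = 0; w < vocab; ++w)
    for (int i = 0; i < dim; ++i) word_out(w, i) = wv[(size_t)w * dim + i];

  return List::create(
      _["doc_vectors"] = doc_out, _["word_vectors"] = word_out,
      _["trace"] = DataFrame::create(
          _["iteration"] = cp_iter, _["loss"] = cp_loss, _["min_dist"] = cp_min,
          _["max_dist"] = cp_max, _["max_dup_dist"] = cp_dup),
      _["diverged"] = diverged);
}
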