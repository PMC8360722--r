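#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <random>
using namespace Rcpp;

// FNV-1a 32-bit over UTF-8 bytes, reduced mod B.  Stable across platforms:
// only fixed-width unsigned arithmetic, and the input is re-encoded to UTF-8
// regardless of the session's native encoding.
// [[Rcpp::export]]
IntegerVector cpp_fnv1a_bucket(CharacterVector x, int B) {
  if (B < 1) stop("B must be >= 1");
  const uint32_t ub = (uint32_t)B;
  int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const char *s = Rf_translateCharUTF8(STRING_ELT(x, i));
    uint32_t h = 2166136261u;
    for (const unsigned char *p = (const unsigned char *)s; *p; ++p) {
      h ^= (uint32_t)(*p);
      h *= 16777619u;
    }
    out[i] = (int)(h % ub);
  }
  return out;
}

// Deterministic model initialization shared by the R (exact softmax) and the
// C++ (negative sampling) training paths: input rows uniform in
// (-0.5/dim, 0.5/dim) drawn column-major from a seeded mt19937, context rows
// zero (word2vec convention).
// [[Rcpp::export]]
List cpp_init_embedding(int n_input, int n_ctx, int dim, int seed) {
  if (dim < 1) stop("dim must be >= 1");
  NumericMatrix A(n_input, dim), U(n_ctx, dim);
  std::mt19937 rng((uint32_t)seed);
  std::uniform_real_distribution<double> unif(-0.5 / dim, 0.5 / dim);
  double *a = REAL(A);
  R_xlen_t na = (R_xlen_t)n_input * dim;
  for (R_xlen_t i = 0; i < na; ++i) a[i] = unif(rng);
  return List::create(_["input"] = A, _["context"] = U);
}

static inline double sgmd(double x) {
  if (x > 8.0) return 1.0 / (1.0 + std::exp(-8.0));
  if (x < -8.0) return 1.0 / (1.0 + std::exp(8.0));
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over substring-set (or whole-word) inputs.
// sentences: token-table indices (0-based) per sentence.
// tok_inputs: per token-table entry, 0-based rows of the input matrix that
//   represent the token (empty = token cannot be a target).
// tok_ctx: per token-table entry, 0-based context-matrix row or -1 (out of
//   vocabulary; such tokens occupy window positions but are never predicted).
// neg_table: 0-based context rows, multiplicity proportional to freq^0.75.
// mean_agg: 1 = represent a target as the mean of its input rows, 0 = sum.
// Single-threaded and deterministic given seed.
// [[Rcpp::export]]
List cpp_train_sgns(List sentences, List tok_inputs, IntegerVector tok_ctx,
                    NumericMatrix input_init, NumericMatrix context_init,
                    int window, int epochs, double alpha, int k,
                    IntegerVector neg_table, int seed, int mean_agg) {
  NumericMatrix A = clone(input_init);
  NumericMatrix U = clone(context_init);
  const int dim = A.ncol();
  const int n_input = A.nrow();
  const int n_ctx = U.nrow();
  const int n_sent = sentences.size();
  const int tsize = neg_table.size();
  if (k > 0 && tsize == 0) stop("negative sampling requires a noise table");

  // row-major working copies keep the per-row inner loops contiguous
  std::vector<double> a((size_t)n_input * dim), u((size_t)n_ctx * dim);
  for (int r = 0; r < n_input; ++r)
    for (int d = 0; d < dim; ++d) a[(size_t)r * dim + d] = A(r, d);
  for (int r = 0; r < n_ctx; ++r)
    for (int d = 0; d < dim; ++d) u[(size_t)r * dim + d] = U(r, d);

  // pre-extract sentence pointers
  std::vector<IntegerVector> sents(n_sent);
  std::vector<IntegerVector> inputs(tok_inputs.size());
  for (int i = 0; i < n_sent; ++i) sents[i] = sentences[i];
  for (int i = 0; i < (int)tok_inputs.size(); ++i) inputs[i] = tok_inputs[i];

  // count trainable pairs per epoch for the learning-rate schedule
  long long pairs_per_epoch = 0;
  for (int si = 0; si < n_sent; ++si) {
    const IntegerVector &s = sents[si];
    const int len = s.size();
    for (int t = 0; t < len; ++t) {
      if (inputs[s[t]].size() == 0) continue;
      for (int j = -window; j <= window; ++j) {
        if (j == 0) continue;
        int p = t + j;
        if (p < 0 || p >= len) continue;
        if (tok_ctx[s[p]] >= 0) ++pairs_per_epoch;
      }
    }
  }
  long long total = pairs_per_epoch * (long long)epochs;
  if (total == 0)
    return List::create(_["input"] = A, _["context"] = U,
                        _["epoch_loss"] = NumericVector(0));

  std::mt19937 rng((uint32_t)seed);
  std::vector<double> h(dim), neu1e(dim);
  NumericVector epoch_loss(epochs);
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    long long loss_n = 0;
    for (int si = 0; si < n_sent; ++si) {
      const IntegerVector &s = sents[si];
      const int len = s.size();
      for (int t = 0; t < len; ++t) {
        const IntegerVector &rows = inputs[s[t]];
        const int ns = rows.size();
        if (ns == 0) continue;
        for (int j = -window; j <= window; ++j) {
          if (j == 0) continue;
          int p = t + j;
          if (p < 0 || p >= len) continue;
          const int ctx = tok_ctx[s[p]];
          if (ctx < 0) continue;
          double lr = alpha * (1.0 - (double)processed / (double)total);
          if (lr < alpha * 1e-4) lr = alpha * 1e-4;
          // target representation
          for (int d = 0; d < dim; ++d) { h[d] = 0.0; neu1e[d] = 0.0; }
          for (int ri = 0; ri < ns; ++ri) {
            const double *arow = &a[(size_t)rows[ri] * dim];
            for (int d = 0; d < dim; ++d) h[d] += arow[d];
          }
          if (mean_agg) for (int d = 0; d < dim; ++d) h[d] /= ns;
          // positive + k negative context rows
          for (int neg = 0; neg <= k; ++neg) {
            int tgt; double label;
            if (neg == 0) { tgt = ctx; label = 1.0; }
            else {
              tgt = neg_table[(int)(rng() % (uint32_t)tsize)];
              if (tgt == ctx) continue;
              label = 0.0;
            }
            double *urow = &u[(size_t)tgt * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += urow[d] * h[d];
            double pr = sgmd(f);
            loss_sum += (label > 0.5) ? -std::log(std::max(pr, 1e-12))
                                      : -std::log(std::max(1.0 - pr, 1e-12));
            double g = (label - pr) * lr;
            for (int d = 0; d < dim; ++d) {
              neu1e[d] += g * urow[d];
              urow[d] += g * h[d];
            }
          }
          // distribute the accumulated gradient over the input rows
          double scale = mean_agg ? 1.0 / ns : 1.0;
          for (int ri = 0; ri < ns; ++ri) {
            double *arow = &a[(size_t)rows[ri] * dim];
            for (int d = 0; d < dim; ++d) arow[d] += neu1e[d] * scale;
          }
          ++processed;
          ++loss_n;
        }
      }
    }
    epoch_loss[ep] = loss_n > 0 ? loss_sum / loss_n : NA_REAL;
  }
  for (int r = 0; r < n_input; ++r)
    for (int d = 0; d < dim; ++d) A(r, d) = a[(size_t)r * dim + d];
  for (int r = 0; r < n_ctx; ++r)
    for (int d = 0; d < dim; ++d) U(r, d) = u[(size_t)r * dim + d];
  return List::create(_["input"] = A, _["context"] = U,
                      _["epoch_loss"] = epoch_loss);
}
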