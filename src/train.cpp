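// Single-threaded trainers for the four embedding methods.
// All randomness comes from an internal xorshift RNG seeded from R, so runs
// are bit-reproducible for a fixed seed.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {
    // splitmix64 warm-up so nearby seeds decorrelate
    for (int i = 0; i < 4; ++i) next();
  }
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// cumulative table for unigram^power negative sampling
struct NegTable {
  std::vector<double> cum;
  explicit NegTable(const NumericVector& counts, double power) {
    cum.resize(counts.size());
    double acc = 0.0;
    for (int i = 0; i < counts.size(); ++i) {
      acc += std::pow(counts[i], power);
      cum[i] = acc;
    }
  }
  int draw(XorShift& rng) const {
    double u = rng.unif() * cum.back();
    int lo = 0, hi = (int)cum.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_train_w2v(List sentences, NumericVector counts, int dim, int window,
                   int negative, double sample, double lr, int epochs,
                   double seed, bool cbow, bool use_ngrams, List ngram_ids,
                   int n_ngrams) {
  const int V = counts.size();
  XorShift rng((uint64_t)seed);
  NegTable neg_table(counts, 0.75);

  double total = 0.0;
  for (int i = 0; i < V; ++i) total += counts[i];

  // per-token keep probability min(1, sqrt(t/f))
  std::vector<double> keep(V, 1.0);
  if (sample > 0) {
    for (int i = 0; i < V; ++i) {
      double f = counts[i] / total;
      double p = std::sqrt(sample / f);
      keep[i] = p < 1.0 ? p : 1.0;
    }
  }

  // input word vectors, output (context) vectors, n-gram input vectors
  std::vector<double> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0);
  std::vector<double> syn0ng((size_t)n_ngrams * dim);
  for (auto& x : syn0) x = (rng.unif() - 0.5) / dim;
  for (auto& x : syn0ng) x = (rng.unif() - 0.5) / dim;

  // flatten n-gram ids (0-based) per word
  std::vector<std::vector<int>> ngrams(V);
  if (use_ngrams) {
    for (int i = 0; i < V; ++i) {
      IntegerVector g = ngram_ids[i];
      ngrams[i].assign(g.begin(), g.end());
    }
  }

  const int S = sentences.size();
  std::vector<std::vector<int>> sents(S);
  double train_words = 0.0;
  for (int s = 0; s < S; ++s) {
    IntegerVector sv = sentences[s];
    sents[s].assign(sv.begin(), sv.end());
    train_words += sv.size();
  }

  NumericVector epoch_loss(epochs);
  std::vector<double> rep(dim), neu1e(dim);
  std::vector<int> kept, ctx;
  double processed = 0.0;
  const double total_budget = train_words * epochs + 1.0;

  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    double loss_n = 0.0;
    for (int s = 0; s < S; ++s) {
      const std::vector<int>& sent = sents[s];
      kept.clear();
      for (int w : sent) {
        ++processed;
        if (keep[w] >= 1.0 || rng.unif() < keep[w]) kept.push_back(w);
      }
      int n = (int)kept.size();
      double alpha = lr * (1.0 - processed / total_budget);
      if (alpha < lr * 1e-4) alpha = lr * 1e-4;

      for (int c = 0; c < n; ++c) {
        int b = 1 + rng.below(window); // dynamic window, uniform 1..window
        int lo = c - b < 0 ? 0 : c - b;
        int hi = c + b >= n ? n - 1 : c + b;
        int center = kept[c];

        if (!cbow) {
          // skip-gram: center word (plus its n-grams) predicts each context
          for (int d = 0; d < dim; ++d) rep[d] = syn0[(size_t)center * dim + d];
          double nng = 0.0;
          if (use_ngrams) {
            for (int g : ngrams[center])
              for (int d = 0; d < dim; ++d) rep[d] += syn0ng[(size_t)g * dim + d];
            nng = (double)ngrams[center].size();
          }
          (void)nng;
          for (int j = lo; j <= hi; ++j) {
            if (j == c) continue;
            int target = kept[j];
            std::fill(neu1e.begin(), neu1e.end(), 0.0);
            for (int k = 0; k <= negative; ++k) {
              int out; double label;
              if (k == 0) { out = target; label = 1.0; }
              else {
                out = neg_table.draw(rng);
                if (out == target) continue;
                label = 0.0;
              }
              double dot = 0.0;
              size_t off = (size_t)out * dim;
              for (int d = 0; d < dim; ++d) dot += rep[d] * syn1[off + d];
              double p = sigmoid(dot);
              loss_sum += label > 0.5 ? -std::log(p > 1e-12 ? p : 1e-12)
                                      : -std::log(1.0 - p > 1e-12 ? 1.0 - p : 1e-12);
              double g = (label - p) * alpha;
              for (int d = 0; d < dim; ++d) {
                neu1e[d] += g * syn1[off + d];
                syn1[off + d] += g * rep[d];
              }
            }
            loss_n += 1.0;
            size_t coff = (size_t)center * dim;
            // the input-side step is normalized by the number of input
            // vectors (word + n-grams), the reference fastText convention;
            // without subwords the divisor is 1
            double inv_in = use_ngrams ? 1.0 / (1.0 + ngrams[center].size()) : 1.0;
            for (int d = 0; d < dim; ++d) syn0[coff + d] += neu1e[d] * inv_in;
            if (use_ngrams)
              for (int g : ngrams[center])
                for (int d = 0; d < dim; ++d)
                  syn0ng[(size_t)g * dim + d] += neu1e[d] * inv_in;
            if (use_ngrams && !ngrams[center].empty())
              for (int d = 0; d < dim; ++d) {
                rep[d] = syn0[coff + d];
                for (int g : ngrams[center]) rep[d] += syn0ng[(size_t)g * dim + d];
              }
            else
              for (int d = 0; d < dim; ++d) rep[d] = syn0[coff + d];
          }
        } else {
          // cbow: mean of context representations predicts the center word
          ctx.clear();
          for (int j = lo; j <= hi; ++j) if (j != c) ctx.push_back(kept[j]);
          if (ctx.empty()) continue;
          std::fill(rep.begin(), rep.end(), 0.0);
          for (int w : ctx) {
            size_t off = (size_t)w * dim;
            for (int d = 0; d < dim; ++d) rep[d] += syn0[off + d];
            if (use_ngrams)
              for (int g : ngrams[w])
                for (int d = 0; d < dim; ++d) rep[d] += syn0ng[(size_t)g * dim + d];
          }
          double inv = 1.0 / (double)ctx.size();
          for (int d = 0; d < dim; ++d) rep[d] *= inv;

          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int out; double label;
            if (k == 0) { out = center; label = 1.0; }
            else {
              out = neg_table.draw(rng);
              if (out == center) continue;
              label = 0.0;
            }
            double dot = 0.0;
            size_t off = (size_t)out * dim;
            for (int d = 0; d < dim; ++d) dot += rep[d] * syn1[off + d];
            double p = sigmoid(dot);
            loss_sum += label > 0.5 ? -std::log(p > 1e-12 ? p : 1e-12)
                                    : -std::log(1.0 - p > 1e-12 ? 1.0 - p : 1e-12);
            double g = (label - p) * alpha;
            for (int d = 0; d < dim; ++d) {
              neu1e[d] += g * syn1[off + d];
              syn1[off + d] += g * rep[d];
            }
          }
          loss_n += 1.0;
          // reference word2vec convention: the full accumulated input-side
          // update is applied to every context word (not divided by the
          // context count)
          for (int w : ctx) {
            size_t off = (size_t)w * dim;
            for (int d = 0; d < dim; ++d) syn0[off + d] += neu1e[d];
            if (use_ngrams)
              for (int g : ngrams[w])
                for (int d = 0; d < dim; ++d)
                  syn0ng[(size_t)g * dim + d] += neu1e[d];
          }
        }
      }
    }
    epoch_loss[ep] = loss_n > 0 ? loss_sum / loss_n : 0.0;
  }

  NumericMatrix W(V, dim), NG(n_ngrams, dim);
  for (int i = 0; i < V; ++i)
    for (int d = 0; d < dim; ++d) W(i, d) = syn0[(size_t)i * dim + d];
  for (int i = 0; i < n_ngrams; ++i)
    for (int d = 0; d < dim; ++d) NG(i, d) = syn0ng[(size_t)i * dim + d];
  return List::create(_["vectors"] = W, _["ngram_vectors"] = NG,
                      _["epoch_loss"] = epoch_loss);
}

// [[Rcpp::export]]
List cpp_build_cooccurrence(List sentences, int vocab_size, int window) {
  std::unordered_map<uint64_t, double> acc;
  const int S = sentences.size();
  for (int s = 0; s < S; ++s) {
    IntegerVector sent = sentences[s];
    int n = sent.size();
    for (int i = 0; i < n; ++i) {
      int hi = i + window < n - 1 ? i + window : n - 1;
      for (int j = i + 1; j <= hi; ++j) {
        double w = 1.0 / (double)(j - i);
        uint64_t a = (uint64_t)sent[i] * vocab_size + sent[j];
        uint64_t b = (uint64_t)sent[j] * vocab_size + sent[i];
        acc[a] += w;
        acc[b] += w;
      }
    }
  }
  int m = (int)acc.size();
  IntegerVector ii(m), jj(m);
  NumericVector xx(m);
  int k = 0;
  for (const auto& kv : acc) {
    ii[k] = (int)(kv.first / vocab_size);
    jj[k] = (int)(kv.first % vocab_size);
    xx[k] = kv.second;
    ++k;
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["x"] = xx);
}

// [[Rcpp::export]]
List cpp_train_glove(IntegerVector ii, IntegerVector jj, NumericVector xx,
                     int vocab_size, int dim, double xmax, double alpha,
                     double lr, int epochs, double seed) {
  const int V = vocab_size, M = ii.size();
  XorShift rng((uint64_t)seed);
  std::vector<double> w((size_t)V * dim), wt((size_t)V * dim);
  std::vector<double> b(V, 0.0), bt(V, 0.0);
  std::vector<double> gw((size_t)V * dim, 1.0), gwt((size_t)V * dim, 1.0);
  std::vector<double> gb(V, 1.0), gbt(V, 1.0);
  for (auto& x : w) x = (rng.unif() - 0.5) / dim;
  for (auto& x : wt) x = (rng.unif() - 0.5) / dim;

  std::vector<int> order(M);
  for (int k = 0; k < M; ++k) order[k] = k;
  std::vector<double> logx(M), fx(M);
  for (int k = 0; k < M; ++k) {
    logx[k] = std::log(xx[k]);
    fx[k] = xx[k] < xmax ? std::pow(xx[k] / xmax, alpha) : 1.0;
  }

  NumericVector epoch_loss(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle of the pair order
    for (int k = M - 1; k > 0; --k) {
      int r = rng.below(k + 1);
      std::swap(order[k], order[r]);
    }
    double loss_sum = 0.0;
    for (int t = 0; t < M; ++t) {
      int k = order[t];
      int a = ii[k], c = jj[k];
      size_t oa = (size_t)a * dim, oc = (size_t)c * dim;
      double diff = b[a] + bt[c] - logx[k];
      for (int d = 0; d < dim; ++d) diff += w[oa + d] * wt[oc + d];
      double f = fx[k];
      loss_sum += f * diff * diff;
      double g = 2.0 * f * diff; // d loss / d (w·w~ + b + b~)
      for (int d = 0; d < dim; ++d) {
        double ga = g * wt[oc + d];
        double gc = g * w[oa + d];
        w[oa + d] -= lr * ga / std::sqrt(gw[oa + d]);
        wt[oc + d] -= lr * gc / std::sqrt(gwt[oc + d]);
        gw[oa + d] += ga * ga;
        gwt[oc + d] += gc * gc;
      }
      b[a] -= lr * g / std::sqrt(gb[a]);
      bt[c] -= lr * g / std::sqrt(gbt[c]);
      gb[a] += g * g;
      gbt[c] += g * g;
    }
    epoch_loss[ep] = loss_sum / M;
  }

  NumericMatrix W(V, dim), WT(V, dim);
  for (int i = 0; i < V; ++i)
    for (int d = 0; d < dim; ++d) {
      W(i, d) = w[(size_t)i * dim + d];
      WT(i, d) = wt[(size_t)i * dim + d];
    }
  return List::create(_["w"] = W, _["w_context"] = WT,
                      _["b"] = NumericVector(b.begin(), b.end()),
                      _["b_context"] = NumericVector(bt.begin(), bt.end()),
                      _["epoch_loss"] = epoch_loss);
}
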