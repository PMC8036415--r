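// Segmentation-lattice primitives for the unigram word-segmentation model.
//
// A sequence of length L defines a lattice over positions 0..L; every
// dictionary word matching residues[i..j) is an edge i -> j weighted by
// log p(word). The forward sum over the lattice is the marginal likelihood
// of the sequence under the unigram model (sum over all segmentations of
// the product of word probabilities); the best path is the Viterbi
// segmentation. These loops dominate dictionary learning, hence C++.

#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double logadd(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log1p(std::exp(-(std::fabs(a - b))));
}

struct Edge { int start; int w; };  // edge [start, end) with word index w

// Per-sequence lattice: in_edges[j] lists edges ending at position j.
struct Lattice {
  int L;
  std::vector<std::vector<Edge> > in_edges;
};

static void build_lattice(const std::string& s,
                          const std::unordered_map<std::string, int>& widx,
                          int lmax, Lattice& lat) {
  int L = (int)s.size();
  lat.L = L;
  lat.in_edges.assign(L + 1, std::vector<Edge>());
  for (int i = 0; i < L; ++i) {
    int maxlen = std::min(lmax, L - i);
    for (int len = 1; len <= maxlen; ++len) {
      std::unordered_map<std::string, int>::const_iterator it =
        widx.find(s.substr(i, len));
      if (it != widx.end()) {
        Edge e; e.start = i; e.w = it->second;
        lat.in_edges[i + len].push_back(e);
      }
    }
  }
}

// Forward log-marginal of one lattice; lp[w] may be NEG_INF (removed word).
// shift is added to every edge weight (used for renormalised pruning).
static double forward_loglik(const Lattice& lat, const std::vector<double>& lp,
                             double shift) {
  std::vector<double> alpha(lat.L + 1, NEG_INF);
  alpha[0] = 0.0;
  for (int j = 1; j <= lat.L; ++j) {
    const std::vector<Edge>& es = lat.in_edges[j];
    double a = NEG_INF;
    for (size_t k = 0; k < es.size(); ++k) {
      double w = lp[es[k].w];
      if (w == NEG_INF || alpha[es[k].start] == NEG_INF) continue;
      a = logadd(a, alpha[es[k].start] + w + shift);
    }
    alpha[j] = a;
  }
  return alpha[lat.L];
}

static std::unordered_map<std::string, int> make_index(const CharacterVector& words) {
  std::unordered_map<std::string, int> widx;
  for (int i = 0; i < words.size(); ++i)
    widx[std::string(words[i])] = i;
  return widx;
}

// [[Rcpp::export]]
NumericVector cpp_corpus_loglik(CharacterVector seqs, CharacterVector words,
                                NumericVector logp, int lmax) {
  std::unordered_map<std::string, int> widx = make_index(words);
  std::vector<double> lp(logp.begin(), logp.end());
  NumericVector out(seqs.size());
  Lattice lat;
  for (int i = 0; i < seqs.size(); ++i) {
    build_lattice(std::string(seqs[i]), widx, lmax, lat);
    out[i] = forward_loglik(lat, lp, 0.0);
  }
  return out;
}

// Forward-backward expected word counts (E-step of EM over segmentations).
// Returns list(counts = per-word expected counts, loglik = total corpus
// log-marginal). Posterior of an edge = exp(alpha[i] + lp[w] + beta[j] - Z).
// [[Rcpp::export]]
List cpp_expected_counts(CharacterVector seqs, CharacterVector words,
                         NumericVector logp, int lmax) {
  std::unordered_map<std::string, int> widx = make_index(words);
  std::vector<double> lp(logp.begin(), logp.end());
  std::vector<double> counts(words.size(), 0.0);
  double total = 0.0;
  Lattice lat;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = std::string(seqs[i]);
    build_lattice(s, widx, lmax, lat);
    int L = lat.L;
    std::vector<double> alpha(L + 1, NEG_INF), beta(L + 1, NEG_INF);
    alpha[0] = 0.0;
    for (int j = 1; j <= L; ++j) {
      const std::vector<Edge>& es = lat.in_edges[j];
      double a = NEG_INF;
      for (size_t k = 0; k < es.size(); ++k)
        if (alpha[es[k].start] != NEG_INF)
          a = logadd(a, alpha[es[k].start] + lp[es[k].w]);
      alpha[j] = a;
    }
    beta[L] = 0.0;
    for (int j = L - 1; j >= 0; --j) beta[j] = NEG_INF;
    // in_edges indexes by end; iterate ends descending so beta[start] uses beta[end]
    for (int j = L; j >= 1; --j) {
      const std::vector<Edge>& es = lat.in_edges[j];
      for (size_t k = 0; k < es.size(); ++k) {
        if (beta[j] == NEG_INF) continue;
        beta[es[k].start] = logadd(beta[es[k].start], lp[es[k].w] + beta[j]);
      }
    }
    double Z = alpha[L];
    if (Z == NEG_INF) stop("unsegmentable sequence in corpus");
    total += Z;
    for (int j = 1; j <= L; ++j) {
      const std::vector<Edge>& es = lat.in_edges[j];
      for (size_t k = 0; k < es.size(); ++k) {
        double post = alpha[es[k].start] + lp[es[k].w] + beta[j] - Z;
        if (post > -700.0) counts[es[k].w] += std::exp(post);
      }
    }
  }
  return List::create(_["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["loglik"] = total);
}

// Viterbi best segmentation. DP runs right-to-left so the path can be
// reconstructed left-to-right with deterministic tie-breaking: among
// score-optimal paths prefer fewer words, then the lexicographically
// smallest word at each step. Ties are detected with an absolute log-score
// tolerance: permutations of one word multiset sum in different orders and
// differ by a few ulps, while genuinely distinct scores under continuous
// probabilities differ by far more.
static const double TIE_EPS = 1e-9;
// [[Rcpp::export]]
CharacterVector cpp_viterbi(std::string s, CharacterVector words,
                            NumericVector logp, int lmax) {
  std::unordered_map<std::string, int> widx = make_index(words);
  std::vector<double> lp(logp.begin(), logp.end());
  int L = (int)s.size();
  // out_edges[i]: edges starting at i
  std::vector<std::vector<std::pair<int, int> > > out_edges(L);  // (len, w)
  for (int i = 0; i < L; ++i) {
    int maxlen = std::min(lmax, L - i);
    for (int len = 1; len <= maxlen; ++len) {
      std::unordered_map<std::string, int>::const_iterator it =
        widx.find(s.substr(i, len));
      if (it != widx.end()) out_edges[i].push_back(std::make_pair(len, it->second));
    }
  }
  std::vector<double> best(L + 1, NEG_INF);
  std::vector<int> nw(L + 1, INT_MAX);
  best[L] = 0.0; nw[L] = 0;
  for (int i = L - 1; i >= 0; --i) {
    for (size_t k = 0; k < out_edges[i].size(); ++k) {
      int j = i + out_edges[i][k].first;
      int w = out_edges[i][k].second;
      if (best[j] == NEG_INF || lp[w] == NEG_INF) continue;
      double cand = lp[w] + best[j];
      if (cand > best[i] + TIE_EPS) {
        best[i] = cand; nw[i] = nw[j] + 1;
      } else if (cand > best[i] - TIE_EPS) {
        if (cand > best[i]) best[i] = cand;
        if (nw[j] + 1 < nw[i]) nw[i] = nw[j] + 1;
      }
    }
  }
  if (best[0] == NEG_INF) stop("sequence not segmentable under the dictionary");
  std::vector<std::string> path;
  int i = 0;
  while (i < L) {
    int pick = -1; std::string pick_word;
    for (size_t k = 0; k < out_edges[i].size(); ++k) {
      int j = i + out_edges[i][k].first;
      int w = out_edges[i][k].second;
      if (best[j] == NEG_INF || lp[w] == NEG_INF) continue;
      if (lp[w] + best[j] > best[i] - TIE_EPS && nw[j] + 1 == nw[i]) {
        std::string ws = std::string(words[w]);
        if (pick < 0 || ws < pick_word) { pick = k; pick_word = ws; }
      }
    }
    if (pick < 0) stop("internal error: Viterbi reconstruction failed");
    path.push_back(pick_word);
    i += out_edges[i][pick].first;
  }
  return wrap(path);
}

// Pruning losses: loss_i = L(dict) - L(dict \ {w_i}, renormalised).
// Removing word i with probability p_i rescales every remaining probability
// by 1/(1 - p_i), i.e. shifts every edge weight by -log(1 - p_i); the
// corpus likelihood is recomputed with word i's edges disabled. Protected
// words (the mononucleotides) get loss NA.
// [[Rcpp::export]]
NumericVector cpp_prune_losses(CharacterVector seqs, CharacterVector words,
                               NumericVector logp, int lmax,
                               LogicalVector protected_word) {
  std::unordered_map<std::string, int> widx = make_index(words);
  std::vector<double> lp(logp.begin(), logp.end());
  int V = words.size(), n = seqs.size();
  std::vector<Lattice> lats(n);
  for (int i = 0; i < n; ++i)
    build_lattice(std::string(seqs[i]), widx, lmax, lats[i]);
  double base = 0.0;
  for (int i = 0; i < n; ++i) base += forward_loglik(lats[i], lp, 0.0);
  NumericVector loss(V, NA_REAL);
  for (int w = 0; w < V; ++w) {
    if (protected_word[w]) continue;
    double p = std::exp(lp[w]);
    double shift = -std::log1p(-p);  // -log(1 - p_w)
    double saved = lp[w];
    lp[w] = NEG_INF;
    double Lw = 0.0;
    bool ok = true;
    for (int i = 0; i < n; ++i) {
      double v = forward_loglik(lats[i], lp, shift);
      if (v == NEG_INF) { ok = false; break; }  // word is load-bearing
      Lw += v;
    }
    lp[w] = saved;
    loss[w] = ok ? (base - Lw) : R_PosInf;
  }
  return loss;
}
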