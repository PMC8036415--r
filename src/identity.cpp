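// Sequence-identity computations for the redundancy filter that replaces
// the external cd-hit-est binary: identity of a pair is the maximum number
// of matching positions over all ungapped slidings, divided by the shorter
// length; filtering is greedy in input order with an 8-mer sharing
// prefilter to skip hopeless alignments.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <string>

using namespace Rcpp;

static double pair_identity_str(const std::string& a, const std::string& b) {
  int la = (int)a.size(), lb = (int)b.size();
  int shorter = la < lb ? la : lb;
  if (shorter == 0) return 0.0;
  int best = 0;
  for (int shift = -(lb - 1); shift <= la - 1; ++shift) {
    // compare a[i] with b[i - shift]
    int i0 = shift > 0 ? shift : 0;
    int i1 = (la < lb + shift ? la : lb + shift);
    int matches = 0;
    for (int i = i0; i < i1; ++i)
      if (a[i] == b[i - shift]) ++matches;
    if (matches > best) best = matches;
  }
  return (double)best / (double)shorter;
}

// [[Rcpp::export]]
double cpp_pair_identity(std::string a, std::string b) {
  return pair_identity_str(a, b);
}

static void kmer_set(const std::string& s, int k,
                     std::unordered_set<unsigned int>& out) {
  if ((int)s.size() < k) return;
  unsigned int code = 0, mask = (1u << (2 * k)) - 1u;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    unsigned int c;
    switch (s[i]) {
      case 'A': c = 0; break; case 'C': c = 1; break;
      case 'G': c = 2; break; default: c = 3; break;
    }
    code = ((code << 2) | c) & mask;
    if (++run >= k) out.insert(code);
  }
}

static bool share_kmer(const std::unordered_set<unsigned int>& a,
                       const std::unordered_set<unsigned int>& b) {
  const std::unordered_set<unsigned int>& small = a.size() < b.size() ? a : b;
  const std::unordered_set<unsigned int>& big = a.size() < b.size() ? b : a;
  for (std::unordered_set<unsigned int>::const_iterator it = small.begin();
       it != small.end(); ++it)
    if (big.count(*it)) return true;
  return false;
}

// Greedy redundancy filter. A candidate is dropped when its identity to any
// reference sequence or any earlier retained candidate reaches the cutoff.
// Returns a logical keep-mask over seqs.
// [[Rcpp::export]]
LogicalVector cpp_redundancy_filter(CharacterVector seqs, double cutoff,
                                    CharacterVector ref, bool prefilter) {
  int k = 8;
  int n = seqs.size();
  LogicalVector keep(n);
  std::vector<std::string> retained;
  std::vector<std::unordered_set<unsigned int> > retained_kmers;
  std::vector<std::string> refs;
  std::vector<std::unordered_set<unsigned int> > ref_kmers;
  for (int i = 0; i < ref.size(); ++i) {
    refs.push_back(std::string(ref[i]));
    ref_kmers.push_back(std::unordered_set<unsigned int>());
    kmer_set(refs.back(), k, ref_kmers.back());
  }
  for (int i = 0; i < n; ++i) {
    std::string s = std::string(seqs[i]);
    std::unordered_set<unsigned int> km;
    kmer_set(s, k, km);
    bool redundant = false;
    for (size_t r = 0; r < refs.size() && !redundant; ++r) {
      if (prefilter && !share_kmer(km, ref_kmers[r])) continue;
      if (pair_identity_str(s, refs[r]) >= cutoff) redundant = true;
    }
    for (size_t r = 0; r < retained.size() && !redundant; ++r) {
      if (prefilter && !share_kmer(km, retained_kmers[r])) continue;
      if (pair_identity_str(s, retained[r]) >= cutoff) redundant = true;
    }
    keep[i] = !redundant;
    if (!redundant) {
      retained.push_back(s);
      retained_kmers.push_back(km);
    }
  }
  return keep;
}
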