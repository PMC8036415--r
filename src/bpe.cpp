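// Byte-pair-encoding seeding for the unigram dictionary: iteratively merge
// the most frequent adjacent symbol pair (ties broken by the
// lexicographically smallest merged string) until the symbol inventory
// reaches seed_size, no pair occurs twice, or every candidate merge would
// exceed l_max characters.

#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_bpe_seed(CharacterVector seqs, int seed_size, int lmax) {
  std::vector<std::string> symbols;  // symbol id -> string
  std::map<std::string, int> sym_id;
  const char* bases = "ACGT";
  for (int b = 0; b < 4; ++b) {
    std::string s(1, bases[b]);
    sym_id[s] = (int)symbols.size();
    symbols.push_back(s);
  }
  // tokenised corpus as symbol ids
  std::vector<std::vector<int> > corpus(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = std::string(seqs[i]);
    corpus[i].reserve(s.size());
    for (size_t j = 0; j < s.size(); ++j)
      corpus[i].push_back(sym_id[std::string(1, s[j])]);
  }
  while ((int)symbols.size() < seed_size) {
    // count adjacent pairs whose merge stays within l_max
    std::unordered_map<long long, int> pair_count;
    for (size_t i = 0; i < corpus.size(); ++i) {
      const std::vector<int>& t = corpus[i];
      for (size_t j = 0; j + 1 < t.size(); ++j) {
        if ((int)(symbols[t[j]].size() + symbols[t[j + 1]].size()) > lmax) continue;
        pair_count[(long long)t[j] * 1000000LL + t[j + 1]] += 1;
      }
    }
    long long best_key = -1; int best_count = 1; std::string best_str;
    for (std::unordered_map<long long, int>::iterator it = pair_count.begin();
         it != pair_count.end(); ++it) {
      if (it->second < 2) continue;
      std::string merged = symbols[(int)(it->first / 1000000LL)] +
                           symbols[(int)(it->first % 1000000LL)];
      if (it->second > best_count ||
          (it->second == best_count && (best_key < 0 || merged < best_str))) {
        best_key = it->first; best_count = it->second; best_str = merged;
      }
    }
    if (best_key < 0) break;  // nothing left worth merging
    int a = (int)(best_key / 1000000LL), b = (int)(best_key % 1000000LL);
    int new_id;
    std::map<std::string, int>::iterator found = sym_id.find(best_str);
    if (found != sym_id.end()) {
      new_id = found->second;  // same string re-derivable via different splits
    } else {
      new_id = (int)symbols.size();
      sym_id[best_str] = new_id;
      symbols.push_back(best_str);
    }
    // greedy left-to-right replacement of the pair
    for (size_t i = 0; i < corpus.size(); ++i) {
      std::vector<int>& t = corpus[i];
      std::vector<int> out;
      out.reserve(t.size());
      size_t j = 0;
      while (j < t.size()) {
        if (j + 1 < t.size() && t[j] == a && t[j + 1] == b) {
          out.push_back(new_id); j += 2;
        } else {
          out.push_back(t[j]); j += 1;
        }
      }
      t.swap(out);
    }
  }
  // token counts of every symbol in the final tokenisation
  std::vector<double> counts(symbols.size(), 0.0);
  for (size_t i = 0; i < corpus.size(); ++i)
    for (size_t j = 0; j < corpus[i].size(); ++j)
      counts[corpus[i][j]] += 1.0;
  return List::create(_["words"] = wrap(symbols),
                      _["counts"] = NumericVector(counts.begin(), counts.end()));
}
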