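#include <Rcpp.h>
#include <array>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Base encoding: A=0, C=1, G=2, T=3.
// Watson-Crick pairs sum to 3 (A+T, C+G); the G:T wobble pair sums to 5
// with both codes >= 2.
static inline bool is_pair(int a, int b, bool gu) {
  if (a + b == 3) return true;
  if (gu && a + b == 5 && a >= 2 && b >= 2) return true;
  return false;
}

struct Cand {
  int i;     // 0-based start of the 5' arm
  int s;     // stem length (base pairs)
  int l;     // loop length (nt)
};

// Maximal perfect hairpins in an encoded sequence.
//
// A candidate (i, s, l) has arms [i, i+s) and [j, j+s), j = i+s+l, with
// arm2 the exact (reverse) complement of arm1 under the allowed pair set.
// It must not be extendable inward (loop shrink by 2 while staying >=
// loop_min) nor outward (one more flanking pair within bounds and span
// limit).  For a fixed 5' arm end e = i+s and loop length l the unique
// maximal stem is min(run, s_cap) where run is the pairing run outward
// from the loop and s_cap = floor((max_span - l) / 2).
//
// Accepted hairpins are selected greedily leftmost-longest (start
// ascending, stem length descending, loop ascending) subject to mutual
// non-overlap of the full [i, j+s) footprints.
//
// [[Rcpp::export]]
IntegerMatrix scan_hairpins_cpp(IntegerVector seq, int stem_min, int loop_min,
                                int loop_max, int max_span, bool allow_gu) {
  const int n = seq.size();
  std::vector<Cand> cand;

  for (int e = stem_min; e + loop_min + stem_min <= n; ++e) {
    for (int l = loop_min; l <= loop_max; ++l) {
      if (e + l + stem_min > n) break;
      // inward-extendable: the two loop-flanking bases themselves pair and
      // the shrunken loop would still be legal
      if (l - 2 >= loop_min && is_pair(seq[e], seq[e + l - 1], allow_gu))
        continue;
      int s_cap = (max_span - l) / 2;
      if (s_cap < stem_min) continue;
      int run = 0;
      while (run < s_cap && e - 1 - run >= 0 && e + l + run < n &&
             is_pair(seq[e - 1 - run], seq[e + l + run], allow_gu))
        ++run;
      if (run >= stem_min) cand.push_back({e - run, run, l});
    }
  }

  std::sort(cand.begin(), cand.end(), [](const Cand& a, const Cand& b) {
    if (a.i != b.i) return a.i < b.i;
    if (a.s != b.s) return a.s > b.s;
    return a.l < b.l;
  });

  std::vector<std::array<int, 7>> acc;
  int last_end = -1;  // intervals are accepted in ascending start order
  for (const Cand& c : cand) {
    int j = c.i + c.s + c.l;
    int end = j + c.s;  // exclusive
    if (c.i < last_end) continue;
    int n_gc = 0, n_at = 0, n_gu = 0;
    for (int t = 0; t < c.s; ++t) {
      int a = seq[c.i + t], b = seq[end - 1 - t];
      if (a + b == 3) {
        if (a == 1 || a == 2) ++n_gc; else ++n_at;
      } else {
        ++n_gu;
      }
    }
    acc.push_back({c.i, j, c.s, c.l, n_gc, n_at, n_gu});
    last_end = end;
  }

  IntegerMatrix out(acc.size(), 7);
  for (size_t r = 0; r < acc.size(); ++r)
    for (int k = 0; k < 7; ++k) out(r, k) = acc[r][k];
  colnames(out) = CharacterVector::create("start_5p", "start_3p", "stem_len",
                                          "loop_len", "n_gc", "n_at", "n_gu");
  return out;
}
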