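#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Optimal chain selection with hit consumption.
//
// Hits arrive in chain space (positions strictly comparable along the scan
// direction), sorted by (pos, probe).  A valid chain has strictly increasing
// probe indices and positions, and every consecutive pair (or every pair
// against the anchor, in anchor mode) deviates from the expected offset gap
// by at most t.  Per round the best chain under the priority
//   (max cardinality, min gap error sum, leftmost anchor, lexicographic)
// is accepted and its hits consumed; rounds stop when the best chain has
// fewer than m hits.

struct DpState {
  int len;
  long long err;
  int anchor;
  int parent;
};

static std::vector<int> reconstruct(const std::vector<DpState>& dp, int j) {
  std::vector<int> chain;
  while (j >= 0) { chain.push_back(j); j = dp[j].parent; }
  std::reverse(chain.begin(), chain.end());
  return chain;
}

// true if chain a is strictly preferred over chain b (equal len & err assumed)
static bool lex_better(const std::vector<int>& a, const std::vector<int>& b,
                       const IntegerVector& pos, const IntegerVector& probe) {
  for (size_t i = 0; i < a.size() && i < b.size(); ++i) {
    if (pos[a[i]] != pos[b[i]]) return pos[a[i]] < pos[b[i]];
    if (probe[a[i]] != probe[b[i]]) return probe[a[i]] < probe[b[i]];
  }
  return false;
}

// [[Rcpp::export(name = ".cpp_chain")]]
List cpp_chain(IntegerVector pos, IntegerVector probe, IntegerVector offsets,
               int t, int m, bool anchor_mode) {
  const int n = pos.size();
  std::vector<bool> alive(n, true);
  List patterns;
  for (;;) {
    std::vector<DpState> dp(n);
    for (int j = 0; j < n; ++j) {
      dp[j].len = alive[j] ? 1 : 0;
      dp[j].err = 0;
      dp[j].anchor = pos[j];
      dp[j].parent = -1;
      if (!alive[j]) continue;
      for (int i = 0; i < j; ++i) {
        if (!alive[i] || dp[i].len == 0) continue;
        if (probe[i] >= probe[j] || pos[i] >= pos[j]) continue;
        int ref = anchor_mode ? dp[i].anchor : pos[i];
        int refprobe;
        if (anchor_mode) {
          // gap measured from the chain anchor's probe
          std::vector<int> ch = reconstruct(dp, i);
          refprobe = probe[ch.front()];
        } else {
          refprobe = probe[i];
        }
        long long gap = (long long)(pos[j] - ref) -
                        (offsets[probe[j]] - offsets[refprobe]);
        long long cost = gap < 0 ? -gap : gap;
        if (cost > t) continue;
        int cand_len = dp[i].len + 1;
        long long cand_err = dp[i].err + cost;
        bool better = false;
        if (cand_len > dp[j].len) better = true;
        else if (cand_len == dp[j].len) {
          if (cand_err < dp[j].err) better = true;
          else if (cand_err == dp[j].err) {
            if (dp[i].anchor < dp[j].anchor) better = true;
            else if (dp[i].anchor == dp[j].anchor && dp[j].parent != i) {
              std::vector<int> a = reconstruct(dp, i);
              a.push_back(j);
              std::vector<int> b = reconstruct(dp, j);
              if (lex_better(a, b, pos, probe)) better = true;
            }
          }
        }
        if (better) {
          dp[j].len = cand_len;
          dp[j].err = cand_err;
          dp[j].anchor = dp[i].anchor;
          dp[j].parent = i;
        }
      }
    }
    int best = -1;
    for (int j = 0; j < n; ++j) {
      if (!alive[j]) continue;
      if (best < 0) { best = j; continue; }
      bool better = false;
      if (dp[j].len > dp[best].len) better = true;
      else if (dp[j].len == dp[best].len) {
        if (dp[j].err < dp[best].err) better = true;
        else if (dp[j].err == dp[best].err) {
          if (dp[j].anchor < dp[best].anchor) better = true;
          else if (dp[j].anchor == dp[best].anchor) {
            std::vector<int> a = reconstruct(dp, j);
            std::vector<int> b = reconstruct(dp, best);
            if (lex_better(a, b, pos, probe)) better = true;
          }
        }
      }
      if (better) best = j;
    }
    if (best < 0 || dp[best].len < m) break;
    std::vector<int> chain = reconstruct(dp, best);
    IntegerVector idx(chain.size());
    for (size_t q = 0; q < chain.size(); ++q) {
      idx[q] = chain[q] + 1;  // 1-based indices into the hit table
      alive[chain[q]] = false;
    }
    patterns.push_back(List::create(_["idx"] = idx,
                                    _["gap_error_sum"] = (double)dp[best].err));
  }
  return patterns;
}
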