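#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// Nucleotide index; anything outside A/C/G/T (notably N) matches no probe base.
static inline int bidx(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return 4;
}

// Best semi-global edit distance of `pat` against any genomic window ending at
// each text position (window start free, end fixed).  Myers bit-vector for
// patterns up to 64 bp, otherwise a plain DP column scan.
static std::vector<int> end_distances(const std::string& text,
                                      const std::string& pat) {
  const int n = (int)text.size(), m = (int)pat.size();
  std::vector<int> out(n);
  if (m <= 64) {
    uint64_t peq[5] = {0, 0, 0, 0, 0};
    for (int i = 0; i < m; ++i) {
      int b = bidx(pat[i]);
      if (b < 4) peq[b] |= (1ULL << i);
    }
    uint64_t pv = ~0ULL, mv = 0ULL;
    const uint64_t hb = 1ULL << (m - 1);
    int score = m;
    for (int j = 0; j < n; ++j) {
      uint64_t eq = peq[bidx(text[j])];
      uint64_t xv = eq | mv;
      uint64_t xh = (((eq & pv) + pv) ^ pv) | eq;
      uint64_t ph = mv | ~(xh | pv);
      uint64_t mh = pv & xh;
      if (ph & hb) ++score; else if (mh & hb) --score;
      // plain shifts: the window start in the text is free
      ph <<= 1;
      mh <<= 1;
      pv = mh | ~(xv | ph);
      mv = ph & xv;
      out[j] = score;
    }
  } else {
    std::vector<int> col(m + 1), nc(m + 1);
    for (int i = 0; i <= m; ++i) col[i] = i;
    for (int j = 0; j < n; ++j) {
      char tc = text[j];
      int tb = bidx(tc);
      nc[0] = 0;  // window start is free
      for (int i = 1; i <= m; ++i) {
        int v = col[i - 1] + ((tb < 4 && pat[i - 1] == tc) ? 0 : 1);
        int d = col[i] + 1;
        int s = nc[i - 1] + 1;
        if (d < v) v = d;
        if (s < v) v = s;
        nc[i] = v;
      }
      col.swap(nc);
      out[j] = col[m];
    }
  }
  return out;
}

// Leftmost window start s such that the global edit distance between `pat` and
// text[s..j] equals d.  Small reversed-DP over at most m+d text characters.
static int leftmost_start(const std::string& text, const std::string& pat,
                          int j, int d) {
  const int m = (int)pat.size();
  int lo = j - (m + d) + 1;
  if (lo < 0) lo = 0;
  std::vector<int> col(m + 1), nc(m + 1);
  for (int i = 0; i <= m; ++i) col[i] = i;
  int best_s = -1;
  for (int idx = 0; idx < j - lo + 1; ++idx) {
    int tj = j - idx;
    char tc = text[tj];
    int tb = bidx(tc);
    nc[0] = idx + 1;  // global alignment: whole window must be consumed
    for (int i = 1; i <= m; ++i) {
      int v = col[i - 1] + ((tb < 4 && pat[m - i] == tc) ? 0 : 1);
      int del = col[i] + 1;
      int ins = nc[i - 1] + 1;
      if (del < v) v = del;
      if (ins < v) v = ins;
      nc[i] = v;
    }
    col.swap(nc);
    if (col[m] == d) best_s = tj;  // keep scanning: smallest start wins
  }
  return best_s;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_end_distances")]]
IntegerVector cpp_end_distances(std::string text, std::string pat) {
  std::vector<int> d = end_distances(text, pat);
  return IntegerVector(d.begin(), d.end());
}

// All hits of `pat` in `text` within edit distance e, one hit per locus:
// qualifying end positions are clustered transitively (ends within e of each
// other share a cluster); each cluster reports its minimum distance, with ties
// resolved by the leftmost alignment start, then the leftmost end.
// [[Rcpp::export(name = ".cpp_find_matches")]]
DataFrame cpp_find_matches(std::string text, std::string pat, int e) {
  const int n = (int)text.size();
  std::vector<int> dist = end_distances(text, pat);
  std::vector<int> pos_out, dist_out, len_out;
  int j = 0;
  while (j < n) {
    if (dist[j] > e) { ++j; continue; }
    // collect one cluster of qualifying ends
    std::vector<int> ends;
    int last = j;
    ends.push_back(j);
    int k2 = j + 1;
    while (k2 < n && k2 - last <= e) {
      if (dist[k2] <= e) { ends.push_back(k2); last = k2; }
      ++k2;
    }
    int dmin = e + 1;
    for (size_t q = 0; q < ends.size(); ++q)
      if (dist[ends[q]] < dmin) dmin = dist[ends[q]];
    int best_s = -1, best_e = -1;
    for (size_t q = 0; q < ends.size(); ++q) {
      if (dist[ends[q]] != dmin) continue;
      int s = leftmost_start(text, pat, ends[q], dmin);
      if (best_s < 0 || s < best_s || (s == best_s && ends[q] < best_e)) {
        best_s = s;
        best_e = ends[q];
      }
    }
    pos_out.push_back(best_s);
    dist_out.push_back(dmin);
    len_out.push_back(best_e - best_s + 1);
    j = last + e + 1;  // first position that cannot belong to this cluster
  }
  return DataFrame::create(_["pos"] = pos_out,
                           _["edit_distance"] = dist_out,
                           _["matched_len"] = len_out);
}
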