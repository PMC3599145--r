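#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Global pairwise alignment with free terminal gaps (overlap/semi-global
// dynamic programming): match +1, mismatch -1, gap -2.  Distance is
// (mismatch columns + internal gap columns) / scored columns, where scored
// columns exclude the leading/trailing free-gap runs.  Ambiguity codes
// (anything outside A/C/G/T) score as mismatches even against themselves.

namespace {

const int MATCH = 1, MISMATCH = -1, GAP = -2;

inline std::vector<uint8_t> encode(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': v[i] = 0; break;
      case 'C': v[i] = 1; break;
      case 'G': v[i] = 2; break;
      case 'T': v[i] = 3; break;
      default:  v[i] = 4; break;  // N and IUPAC ambiguity: never matches
    }
  }
  return v;
}

struct AlnStats {
  double score, distance;
  int mismatches, internal_gaps, scored_columns;
};

AlnStats nw_overlap(const std::vector<uint8_t>& a, const std::vector<uint8_t>& b,
                    std::vector<int16_t>& S) {
  const int n = (int)a.size(), m = (int)b.size();
  const int w = m + 1;
  S.assign((size_t)(n + 1) * w, 0);
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    const int16_t* Sp = &S[(size_t)(i - 1) * w];
    int16_t* Sc = &S[(size_t)i * w];
    for (int j = 1; j <= m; ++j) {
      const int16_t sub = (ai == b[j - 1] && ai < 4) ? MATCH : MISMATCH;
      int16_t best = (int16_t)(Sp[j - 1] + sub);
      const int16_t up = (int16_t)(Sp[j] + GAP);
      if (up > best) best = up;
      const int16_t left = (int16_t)(Sc[j - 1] + GAP);
      if (left > best) best = left;
      Sc[j] = best;
    }
  }
  // Free trailing gaps: best cell on the last row or last column.  Scan
  // order fixes ties deterministically: (n,m), then last row right-to-left,
  // then last column bottom-to-top.
  int bi = n, bj = m, best = S[(size_t)n * w + m];
  for (int j = m - 1; j >= 0; --j)
    if (S[(size_t)n * w + j] > best) { best = S[(size_t)n * w + j]; bi = n; bj = j; }
  for (int i = n - 1; i >= 0; --i)
    if (S[(size_t)i * w + m] > best) { best = S[(size_t)i * w + m]; bi = i; bj = m; }

  AlnStats st; st.score = best;
  // Traceback re-derives each move from S, preferring diagonal, then up
  // (gap in b), then left (gap in a) — the same order used when filling.
  int mis = 0, gaps = 0, cols = 0;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    const int16_t cur = S[(size_t)i * w + j];
    const bool eq = (a[i - 1] == b[j - 1] && a[i - 1] < 4);
    ++cols;
    if (cur == S[(size_t)(i - 1) * w + (j - 1)] + (eq ? MATCH : MISMATCH)) {
      if (!eq) ++mis;
      --i; --j;
    } else if (cur == S[(size_t)(i - 1) * w + j] + GAP) { ++gaps; --i; }
    else { ++gaps; --j; }
  }
  st.mismatches = mis; st.internal_gaps = gaps; st.scored_columns = cols;
  st.distance = cols > 0 ? (double)(mis + gaps) / cols : 1.0;
  return st;
}

} // namespace

// [[Rcpp::export(name = ".nw_align_stats")]]
List nw_align_stats_cpp(std::string a, std::string b) {
  std::vector<int16_t> S;
  std::vector<uint8_t> ea = encode(a), eb = encode(b);
  AlnStats st = nw_overlap(ea, eb, S);
  return List::create(_["score"] = st.score,
                      _["distance"] = st.distance,
                      _["mismatches"] = st.mismatches,
                      _["internal_gaps"] = st.internal_gaps,
                      _["scored_columns"] = st.scored_columns);
}

// All unordered pairs i<j; pairs with distance >= cutoff are dropped
// (cutoff = Inf keeps everything).  Indices returned 1-based.
// [[Rcpp::export(name = ".nw_all_pairs")]]
DataFrame nw_all_pairs_cpp(CharacterVector seqs, double cutoff) {
  const int n = seqs.size();
  std::vector<std::vector<uint8_t> > enc(n);
  for (int i = 0; i < n; ++i) enc[i] = encode(as<std::string>(seqs[i]));
  std::vector<int16_t> S;
  std::vector<int> ii, jj; std::vector<double> dd;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      AlnStats st = nw_overlap(enc[i], enc[j], S);
      if (st.distance < cutoff) {
        ii.push_back(i + 1); jj.push_back(j + 1); dd.push_back(st.distance);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["d"] = dd);
}
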