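#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdlib>
using namespace Rcpp;

// Banded unit-cost Levenshtein distance with cap. Returns cap+1 when the true
// distance exceeds cap. Cells with |i-j| > cap cannot contribute to a path of
// cost <= cap, so only the diagonal band is evaluated.
static int lev_banded(const char* a, int la, const char* b, int lb, int cap) {
  if (std::abs(la - lb) > cap) return cap + 1;
  const int BIG = cap + 1;
  std::vector<int> prev(lb + 1, BIG), cur(lb + 1, BIG);
  for (int j = 0; j <= std::min(lb, cap); ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    int jlo = std::max(1, i - cap), jhi = std::min(lb, i + cap);
    std::fill(cur.begin(), cur.end(), BIG);
    if (jlo == 1) cur[0] = (i <= cap) ? i : BIG;
    int rowmin = cur[0];
    for (int j = jlo; j <= jhi; ++j) {
      int d = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      if (prev[j] + 1 < d) d = prev[j] + 1;
      if (cur[j - 1] + 1 < d) d = cur[j - 1] + 1;
      if (d > BIG) d = BIG;
      cur[j] = d;
      if (d < rowmin) rowmin = d;
    }
    if (rowmin >= BIG) return BIG;
    std::swap(prev, cur);
  }
  return std::min(prev[lb], BIG);
}

// [[Rcpp::export(name = ".lev_matrix")]]
IntegerMatrix lev_matrix_cpp(CharacterVector segments, CharacterVector barcodes, int cap) {
  int n = segments.size(), m = barcodes.size();
  std::vector<std::string> bc(m);
  for (int j = 0; j < m; ++j) bc[j] = as<std::string>(barcodes[j]);
  IntegerMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(segments[i]);
    for (int j = 0; j < m; ++j)
      out(i, j) = lev_banded(s.c_str(), (int)s.size(), bc[j].c_str(), (int)bc[j].size(), cap);
  }
  return out;
}

// Semi-global alignment: the pattern is aligned end-to-end, the text has free
// ends. Unit costs. Returns, per text, the minimal edit distance, and the
// 1-based start/end of the consumed text window (leftmost best end; ties on
// start resolved toward the diagonal predecessor).
// [[Rcpp::export(name = ".semiglobal")]]
DataFrame semiglobal_cpp(std::string pattern, CharacterVector texts) {
  int m = (int)pattern.size();
  int n = texts.size();
  IntegerVector dist(n), start(n), end(n);
  for (int t = 0; t < n; ++t) {
    std::string txt = as<std::string>(texts[t]);
    int L = (int)txt.size();
    std::vector<int> dprev(L + 1), dcur(L + 1), sprev(L + 1), scur(L + 1);
    for (int j = 0; j <= L; ++j) { dprev[j] = 0; sprev[j] = j; }
    for (int i = 1; i <= m; ++i) {
      dcur[0] = i; scur[0] = 0;
      for (int j = 1; j <= L; ++j) {
        int diag = dprev[j - 1] + (pattern[i - 1] == txt[j - 1] ? 0 : 1);
        int up = dprev[j] + 1;      // gap in text (pattern char unmatched)
        int left = dcur[j - 1] + 1; // gap in pattern (text char skipped)
        int d = diag, s = sprev[j - 1];
        if (up < d) { d = up; s = sprev[j]; }
        if (left < d) { d = left; s = scur[j - 1]; }
        dcur[j] = d; scur[j] = s;
      }
      std::swap(dprev, dcur);
      std::swap(sprev, scur);
    }
    int best = dprev[0], bj = 0;
    for (int j = 1; j <= L; ++j) if (dprev[j] < best) { best = dprev[j]; bj = j; }
    dist[t] = best;
    start[t] = sprev[bj] + 1;
    end[t] = bj;
  }
  return DataFrame::create(_["dist"] = dist, _["start"] = start, _["end"] = end);
}

// Greedy scan keeping candidates whose Hamming distance to every previously
// kept string (and every string in `existing`) is >= min_d.
// [[Rcpp::export(name = ".greedy_min_hamming")]]
LogicalVector greedy_min_hamming_cpp(CharacterVector cands, int min_d, CharacterVector existing) {
  int n = cands.size();
  std::vector<std::string> kept;
  for (int j = 0; j < existing.size(); ++j) kept.push_back(as<std::string>(existing[j]));
  LogicalVector keep(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(cands[i]);
    bool ok = true;
    for (size_t k = 0; k < kept.size() && ok; ++k) {
      if (kept[k].size() != s.size()) continue;
      int d = 0;
      for (size_t p = 0; p < s.size(); ++p) {
        if (s[p] != kept[k][p] && ++d >= min_d) break;
      }
      if (d < min_d) ok = false;
    }
    keep[i] = ok;
    if (ok) kept.push_back(s);
  }
  return keep;
}

// [[Rcpp::export(name = ".min_pairwise_hamming")]]
int min_pairwise_hamming_cpp(CharacterVector x) {
  int n = x.size();
  if (n < 2) return NA_INTEGER;
  std::vector<std::string> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<std::string>(x[i]);
  int best = (int)v[0].size();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int d = 0;
      for (size_t p = 0; p < v[i].size(); ++p) {
        if (v[i][p] != v[j][p] && ++d >= best) break;
      }
      if (d < best) best = d;
      if (best == 0) return 0;
    }
  return best;
}

// Pairwise Hamming distances among equal-length strings (small groups; UMIs).
// [[Rcpp::export(name = ".hamming_matrix")]]
IntegerMatrix hamming_matrix_cpp(CharacterVector x) {
  int n = x.size();
  std::vector<std::string> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<std::string>(x[i]);
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int d = 0;
      for (size_t p = 0; p < v[i].size(); ++p) if (v[i][p] != v[j][p]) ++d;
      out(i, j) = d; out(j, i) = d;
    }
  return out;
}
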