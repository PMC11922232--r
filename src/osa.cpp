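#include <Rcpp.h>
#include <string>
#include <vector>
#include <cstdlib>

using namespace Rcpp;

// Optimal string alignment (restricted Damerau-Levenshtein) distance:
// insert, delete, substitute, adjacent transposition; no substring is
// edited more than once. Three rolling rows, reused across calls; when
// cap >= 0, returns cap + 1 as soon as the distance must exceed cap.
static int osa_one(const std::string& a, const std::string& b, int cap) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (cap >= 0 && std::abs(la - lb) > cap) return cap + 1;
  static std::vector<int> r0, r1, r2;
  if ((int)r0.size() < lb + 1) {
    r0.resize(lb + 1);
    r1.resize(lb + 1);
    r2.resize(lb + 1);
  }
  for (int j = 0; j <= lb; ++j) r1[j] = j;
  for (int i = 1; i <= la; ++i) {
    r2[0] = i;
    int row_min = i;
    for (int j = 1; j <= lb; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int v = r1[j - 1] + cost;
      if (r1[j] + 1 < v) v = r1[j] + 1;
      if (r2[j - 1] + 1 < v) v = r2[j - 1] + 1;
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1]) {
        if (r0[j - 2] + 1 < v) v = r0[j - 2] + 1;
      }
      r2[j] = v;
      if (v < row_min) row_min = v;
    }
    if (cap >= 0 && row_min > cap) return cap + 1;
    std::swap(r0, r1);
    std::swap(r1, r2);
  }
  return r1[lb];
}

// [[Rcpp::export(name = ".osa_dist_cpp")]]
IntegerVector osa_dist_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("a and b must have the same length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    out[i] = osa_one(as<std::string>(a[i]), as<std::string>(b[i]), -1);
  }
  return out;
}

// All (candidate, term) pairs with distance <= max_dist[term]; length
// difference pruning makes the candidate x term sweep cheap.
// [[Rcpp::export(name = ".osa_match_cpp")]]
DataFrame osa_match_cpp(CharacterVector cands, CharacterVector terms,
                        IntegerVector max_dist) {
  if (terms.size() != max_dist.size()) stop("terms and max_dist lengths differ");
  std::vector<int> ci, ti, dd;
  const R_xlen_t nt = terms.size();
  std::vector<std::string> tv(nt);
  for (R_xlen_t j = 0; j < nt; ++j) tv[j] = as<std::string>(terms[j]);
  for (R_xlen_t i = 0; i < cands.size(); ++i) {
    std::string c = as<std::string>(cands[i]);
    const int lc = (int)c.size();
    for (R_xlen_t j = 0; j < nt; ++j) {
      const int cap = max_dist[j];
      if (std::abs(lc - (int)tv[j].size()) > cap) continue;
      int dist = osa_one(c, tv[j], cap);
      if (dist <= cap) {
        ci.push_back((int)i + 1);
        ti.push_back((int)j + 1);
        dd.push_back(dist);
      }
    }
  }
  return DataFrame::create(_["cand"] = ci, _["term"] = ti, _["distance"] = dd);
}
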