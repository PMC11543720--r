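#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Optimal string alignment (restricted Damerau-Levenshtein) distance with
// unit costs. Standard O(nm) dynamic program; adjacent transpositions are
// allowed but a transposed substring is never edited again.
static int osa_one(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> d((n + 1) * (m + 1));
  const int w = m + 1;
  for (int i = 0; i <= n; ++i) d[i * w] = i;
  for (int j = 0; j <= m; ++j) d[j] = j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int best = std::min(std::min(d[(i - 1) * w + j] + 1,   // deletion
                                   d[i * w + j - 1] + 1),    // insertion
                          d[(i - 1) * w + j - 1] + cost);    // substitution
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        best = std::min(best, d[(i - 2) * w + j - 2] + 1);   // transposition
      d[i * w + j] = best;
    }
  }
  return d[n * w + m];
}

// [[Rcpp::export]]
IntegerVector cpp_osa_distance(CharacterVector s1, CharacterVector s2) {
  const R_xlen_t n = std::max(s1.size(), s2.size());
  if (s1.size() != n && s1.size() != 1) stop("length mismatch");
  if (s2.size() != n && s2.size() != 1) stop("length mismatch");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string a = as<std::string>(s1[s1.size() == 1 ? 0 : i]);
    std::string b = as<std::string>(s2[s2.size() == 1 ? 0 : i]);
    out[i] = osa_one(a, b);
  }
  return out;
}

// Distance from each query to each lexicon word; rows = queries.
// [[Rcpp::export]]
IntegerMatrix cpp_osa_matrix(CharacterVector queries, CharacterVector words) {
  IntegerMatrix out(queries.size(), words.size());
  std::vector<std::string> ws(words.size());
  for (R_xlen_t j = 0; j < words.size(); ++j) ws[j] = as<std::string>(words[j]);
  for (R_xlen_t i = 0; i < queries.size(); ++i) {
    const std::string q = as<std::string>(queries[i]);
    for (R_xlen_t j = 0; j < words.size(); ++j) out(i, j) = osa_one(q, ws[j]);
  }
  return out;
}

// One pass of Elo-style value learning over implied best/worst pairs.
// values is updated in place (passed by value, returned): expected win
// probability follows the logistic rule p = 1 / (1 + 10^((v_l - v_w)/s)).
// `order` is a 1-based permutation of the pair indices.
// [[Rcpp::export]]
NumericVector cpp_value_learning_pass(NumericVector values,
                                      IntegerVector winner,
                                      IntegerVector loser,
                                      IntegerVector order,
                                      double eta, double s) {
  NumericVector v = clone(values);
  const R_xlen_t np = order.size();
  for (R_xlen_t k = 0; k < np; ++k) {
    const int idx = order[k] - 1;
    const int w = winner[idx] - 1;
    const int l = loser[idx] - 1;
    const double p = 1.0 / (1.0 + std::pow(10.0, (v[l] - v[w]) / s));
    const double delta = eta * (1.0 - p);
    v[w] += delta;
    v[l] -= delta;
  }
  return v;
}
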