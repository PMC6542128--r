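#include <Rcpp.h>
#include <array>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Interval dynamic programming over nested (pseudoknot-free) structures.
//
// Both routines take an n x n matrix prepared in R that already encodes the
// energy model and the admissibility rules (complementarity, optional GU,
// minimum hairpin size theta): entries for inadmissible pairs are +Inf
// (Nussinov energies) or 0 (Boltzmann weights).

// Minimum-energy structure. en(i,j), 0-based, holds the additive pair energy
// for admissible (i,j) and +Inf otherwise. Deterministic traceback: when the
// optimum is attainable both by leaving j unpaired and by pairing j, pairing
// wins; among pairing partners the smallest k wins.
// [[Rcpp::export]]
List nussinov_cpp(NumericMatrix en) {
  int n = en.nrow();
  NumericMatrix E(n, n);          // E(i,j): optimum over closed interval [i,j]
  IntegerMatrix choice(n, n);     // -1: j unpaired, else k paired with j
  std::fill(choice.begin(), choice.end(), -1);
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best_unpaired = E(i, j - 1);
      double best_pair = R_PosInf;
      int best_k = -1;
      for (int k = i; k < j; ++k) {
        double e = en(k, j);
        if (!R_finite(e)) continue;
        double cand = e;
        if (k > i) cand += E(i, k - 1);
        if (k + 1 <= j - 1) cand += E(k + 1, j - 1);
        if (cand < best_pair) { best_pair = cand; best_k = k; }
      }
      if (best_k >= 0 && best_pair <= best_unpaired) {
        E(i, j) = best_pair;
        choice(i, j) = best_k;
      } else {
        E(i, j) = best_unpaired;
      }
    }
  }
  std::vector<int> pi, pj;
  std::vector<std::pair<int, int> > stack;
  if (n >= 2) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    std::pair<int, int> iv = stack.back();
    stack.pop_back();
    int i = iv.first, j = iv.second;
    if (i >= j) continue;
    int k = choice(i, j);
    if (k < 0) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    pi.push_back(k + 1);  // report 1-based
    pj.push_back(j + 1);
    if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
    if (k > i) stack.push_back(std::make_pair(i, k - 1));
  }
  double emin = (n >= 2) ? E(0, n - 1) : 0.0;
  return List::create(_["energy"] = emin, _["i"] = wrap(pi), _["j"] = wrap(pj));
}

// Partition function and pair probabilities. w(i,j), 0-based, holds the
// Boltzmann weight of an admissible pair and 0 otherwise.
//   Q(i,j)  = Q(i,j-1) + sum_k Q(i,k-1) * Qb(k,j)
//   Qb(k,j) = w(k,j) * Q(k+1,j-1)
// with Q = 1 on empty intervals; the outside pass distributes each pair's
// exterior weight either through the unpaired exterior or through every
// admissible enclosing pair, visited in order of decreasing span.
// [[Rcpp::export]]
List mccaskill_cpp(NumericMatrix w) {
  int n = w.nrow();
  NumericMatrix Q(n + 2, n + 2), Qb(n + 2, n + 2);
  // 1-based interval lookup; empty interval contributes weight 1.
#define QI(i, j) (((i) > (j)) ? 1.0 : Q((i), (j)))
  for (int len = 1; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      double acc = QI(i, j - 1);
      for (int k = i; k < j; ++k) {
        double wk = w(k - 1, j - 1);
        if (wk <= 0) continue;
        double qb = wk * QI(k + 1, j - 1);
        Qb(k, j) = qb;
        acc += QI(i, k - 1) * qb;
      }
      Q(i, j) = acc;
    }
  }
  double Qtot = QI(1, n);
  if (!R_finite(Qtot)) stop("partition function overflowed double precision");

  std::vector<std::array<int, 2> > prs;
  for (int i = 1; i <= n; ++i)
    for (int j = i + 1; j <= n; ++j)
      if (w(i - 1, j - 1) > 0) prs.push_back({{i, j}});
  std::sort(prs.begin(), prs.end(),
            [](const std::array<int, 2>& a, const std::array<int, 2>& b) {
              if (a[1] - a[0] != b[1] - b[0]) return (a[1] - a[0]) > (b[1] - b[0]);
              return a[0] < b[0];
            });

  NumericMatrix P(n + 1, n + 1);
  for (size_t u = 0; u < prs.size(); ++u) {
    int i = prs[u][0], j = prs[u][1];
    double qb = Qb(i, j);
    if (qb <= 0) continue;
    double ext = QI(1, i - 1) * QI(j + 1, n) / Qtot;
    double inner = 0.0;
    for (size_t v = 0; v < u; ++v) {  // enclosing pairs have larger span
      int k = prs[v][0], l = prs[v][1];
      if (k >= i || l <= j) continue;
      double pkl = P(k, l);
      if (pkl <= 0) continue;
      inner += pkl * QI(k + 1, i - 1) * QI(j + 1, l - 1) / QI(k + 1, l - 1);
    }
    P(i, j) = qb * (ext + inner);
  }
#undef QI

  std::vector<int> oi, oj;
  std::vector<double> op;
  for (size_t u = 0; u < prs.size(); ++u) {
    double v = P(prs[u][0], prs[u][1]);
    if (v > 0) {
      oi.push_back(prs[u][0]);
      oj.push_back(prs[u][1]);
      op.push_back(v);
    }
  }
  return List::create(_["Q"] = Qtot, _["i"] = wrap(oi), _["j"] = wrap(oj),
                      _["p"] = wrap(op));
}
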