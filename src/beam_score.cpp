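#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Objective of one candidate gene table under the negative-fraction cap,
// using the greedy selection (all non-positive-weight genes first, then
// positive-weight genes in decreasing contribution order while the
// accumulated slack covers their excess negatives). This mirrors the greedy
// path of select_genes() and is the state score used inside the beam search.
static double greedy_objective(const std::vector<double>& cont,
                               const std::vector<int>& negs,
                               double t_allow) {
  double obj = 0.0, slack = 0.0;
  std::vector<int> heavy;
  heavy.reserve(cont.size());
  for (size_t i = 0; i < cont.size(); ++i) {
    if (negs[i] <= t_allow) {
      obj += cont[i];
      slack += t_allow - negs[i];
    } else {
      heavy.push_back((int)i);
    }
  }
  if (!heavy.empty()) {
    std::sort(heavy.begin(), heavy.end(), [&](int a, int b) {
      if (cont[a] != cont[b]) return cont[a] > cont[b];
      return a < b;
    });
    const double tol = 1e-9;
    for (int i : heavy) {
      double w = negs[i] - t_allow;
      if (w <= slack + tol) {
        obj += cont[i];
        slack -= w;
      }
    }
  }
  return obj;
}

// Score every one-cell extension of a beam state.
//
// m, mpos: genes x cells log-expression and its positive part.
// omega_base: genes x samples specificity scores of the current state
//   (out-of-cluster penalties already included).
// neg: per-gene negative-entry counts within the current cell set.
// cand: 0-based candidate cell columns; cand_sample: 0-based sample index
//   of each candidate. j_size: current |J|.
// gain_max: per-gene upper bound, over the candidate pool, of
//   m(g,j) + kappa * mpos(g,j) (the exact change of the gene's score-sum
//   when cell j joins the state). Since the consistency weight is strictly
//   positive, a gene can contribute iff its new score-sum is positive, so
//   genes with sum_omega + gain_max <= 0 are skipped up front.
// Returns the greedy objective of J + {candidate}; on the zero-objective
// plateau (no profitable gene), the best single-gene contribution instead,
// so the search can rank states by how close they are to profitability.
// [[Rcpp::export(name = ".score_extensions")]]
NumericVector score_extensions(const NumericMatrix& m,
                               const NumericMatrix& mpos,
                               const NumericMatrix& omega_base,
                               const IntegerVector& neg,
                               const IntegerVector& cand,
                               const IntegerVector& cand_sample,
                               const NumericVector& gain_max,
                               int j_size, double kappa, double mu,
                               double eps) {
  const int G = m.nrow();
  const int S = omega_base.ncol();
  const int nc = cand.size();
  NumericVector out(nc);

  // Per-gene aggregates of the base state, reused across candidates.
  std::vector<double> sum_omega(G, 0.0), sum_clip(G, 0.0), log_clip(G, 0.0);
  std::vector<std::vector<double>> clip_base(S, std::vector<double>(G));
  for (int s = 0; s < S; ++s) {
    for (int g = 0; g < G; ++g) {
      double w = omega_base(g, s);
      double c = w > eps ? w : eps;
      clip_base[s][g] = c;
      sum_omega[g] += w;
      sum_clip[g] += c;
      if (S > 2) log_clip[g] += std::log(c);
    }
  }

  // Genes that can reach a positive score-sum for at least one candidate.
  std::vector<int> act;
  act.reserve(G);
  for (int g = 0; g < G; ++g) {
    if (sum_omega[g] + gain_max[g] > 0.0) act.push_back(g);
  }

  const double t_allow = mu * (j_size + 1);
  std::vector<double> cont;
  std::vector<int> negs;
  cont.reserve(act.size());
  negs.reserve(act.size());

  auto contribution = [&](int g, int j, int sj) -> double {
    const double mg = m(g, j);
    const double wold = omega_base(g, sj);
    const double wnew = wold + mg + kappa * mpos(g, j);
    const double cold = clip_base[sj][g];
    const double cnew = wnew > eps ? wnew : eps;
    const double sumw = sum_omega[g] - wold + wnew;
    double delta;
    if (S == 1) {
      delta = 1.0;
    } else if (S == 2) {
      const double other = sum_clip[g] - cold;
      delta = 2.0 * std::sqrt(cnew * other) / (cnew + other);
    } else {
      const double ls = log_clip[g] - std::log(cold) + std::log(cnew);
      const double sc = sum_clip[g] - cold + cnew;
      delta = std::exp(ls / S) / (sc / S);
    }
    if (delta > 1.0) delta = 1.0;  // AM-GM bound, clamp numerical noise
    return delta * sumw;
  };

  for (int k = 0; k < nc; ++k) {
    const int j = cand[k];
    const int sj = cand_sample[k];
    cont.clear();
    negs.clear();
    for (int g : act) {
      // exact positivity test: score-sum change is m + kappa * mpos
      if (sum_omega[g] + m(g, j) + kappa * mpos(g, j) <= 0.0) continue;
      const double c = contribution(g, j, sj);
      if (c > 0.0) {
        cont.push_back(c);
        negs.push_back(neg[g] + (m(g, j) < 0.0 ? 1 : 0));
      }
    }
    double obj = greedy_objective(cont, negs, t_allow);
    if (obj <= 0.0) {
      // Plateau: rank by the best single-gene contribution. Since the
      // consistency weight is at most 1, c <= score-sum, so only the genes
      // with the largest new score-sums can carry the maximum; evaluate
      // the exact contribution for the top candidates only (all genes when
      // there are few, as in small instances).
      const int T = 32;
      double max_c = -std::numeric_limits<double>::infinity();
      if (G <= T) {
        for (int g = 0; g < G; ++g) {
          const double c = contribution(g, j, sj);
          if (c > max_c) max_c = c;
        }
      } else {
        std::vector<std::pair<double, int>> sums(G);
        for (int g = 0; g < G; ++g) {
          sums[g] = {sum_omega[g] + m(g, j) + kappa * mpos(g, j), g};
        }
        std::partial_sort(sums.begin(), sums.begin() + T, sums.end(),
                          [](const std::pair<double, int>& a,
                             const std::pair<double, int>& b) {
                            if (a.first != b.first) return a.first > b.first;
                            return a.second < b.second;
                          });
        for (int t = 0; t < T; ++t) {
          const double c = contribution(sums[t].second, j, sj);
          if (c > max_c) max_c = c;
        }
      }
      obj = std::min(max_c, 0.0);
    }
    out[k] = obj;
  }
  return out;
}
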