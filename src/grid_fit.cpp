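// Exhaustive grid-search likelihood evaluation for the gain-loss Q-learning
// model.  The likelihood of a session factorizes exactly into a reward-trial
// term (depending on LR+, LR-, beta, R0rew only) and a punishment-trial term
// (LR+, LR-, beta, R0pun only), because every stimulus carries its own pair
// of Q-values and R0 enters only through that stimulus type's no-feedback
// outcomes.  We therefore tabulate two 4-D negLLE arrays and combine them
// per model variant; the R-level naive loop is the test oracle for this path.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <tuple>
#include <functional>

using namespace Rcpp;

static inline double log1pexp_(double x) {
  // log(1 + exp(x)), stable for large |x|
  if (x > 33.3) return x;
  if (x > 18.0) return x + std::exp(-x);
  if (x > -37.0) return std::log1p(std::exp(x));
  return std::exp(x);
}

// negLLE contribution of one trial given d = Q(chosen) - Q(other) and beta.
static inline double nll_term(double d, double beta) {
  if (beta == 0.0) {
    if (d > 0.0) return 0.0;
    if (d < 0.0) return std::numeric_limits<double>::infinity();
    return M_LN2;
  }
  return log1pexp_(-d / beta);
}

// Tabulate negLLE over (lr+, lr-, beta, r0) for one trial-type group.
// stim01: 0/1 index of the stimulus within the group; chosen: 0 (A) / 1 (B);
// rexp: explicit outcome value (+1/-1) or NA for the no-feedback outcome.
// Output layout: a[i + nl*(j + nl*(b + nb*r))].
static std::vector<double> group_table(const IntegerVector& stim01,
                                       const IntegerVector& chosen,
                                       const NumericVector& rexp,
                                       const NumericVector& lr,
                                       const NumericVector& betag,
                                       const NumericVector& r0g) {
  const int nt = stim01.size();
  const int nl = lr.size(), nb = betag.size(), nr = r0g.size();
  std::vector<double> out((size_t)nl * nl * nb * nr, 0.0);
  std::vector<double> d(nt);
  for (int r = 0; r < nr; ++r) {
    const double r0 = r0g[r];
    for (int j = 0; j < nl; ++j) {
      const double lrm = lr[j];
      for (int i = 0; i < nl; ++i) {
        const double lrp = lr[i];
        double q[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
        for (int t = 0; t < nt; ++t) {
          const int s = stim01[t], c = chosen[t];
          d[t] = q[s][c] - q[s][1 - c];
          const double R = ISNAN(rexp[t]) ? r0 : rexp[t];
          const double pe = R - q[s][c];
          if (pe > 0.0) q[s][c] += lrp * pe;
          else if (pe < 0.0) q[s][c] += lrm * pe;
        }
        for (int b = 0; b < nb; ++b) {
          const double beta = betag[b];
          double acc = 0.0;
          for (int t = 0; t < nt; ++t) acc += nll_term(d[t], beta);
          out[(size_t)i + (size_t)nl * (j + (size_t)nl * (b + (size_t)nb * r))] = acc;
        }
      }
    }
  }
  return out;
}

// stim: 1..4; resp: 1 = A, 2 = B; outc: 1 reward, 2 punishment, 3 none.
// variant: 1 five_param, 2 r0_shared, 3 r0_inv, 4 r0_zero, 5 single_lr.
// [[Rcpp::export(name = ".grid_search_cpp")]]
List grid_search_cpp(IntegerVector stim, IntegerVector resp,
                     IntegerVector outc, NumericVector lr_grid,
                     NumericVector beta_grid, NumericVector r0_rew_grid,
                     NumericVector r0_pun_grid, int variant, double tol,
                     int max_ties) {
  const int nt = stim.size();
  std::vector<int> rs, ps;   // trial indices per group
  for (int t = 0; t < nt; ++t) {
    if (stim[t] <= 2) rs.push_back(t); else ps.push_back(t);
  }
  auto build = [&](const std::vector<int>& idx, bool reward_group) {
    IntegerVector s01(idx.size()), ch(idx.size());
    NumericVector re(idx.size());
    for (size_t u = 0; u < idx.size(); ++u) {
      int t = idx[u];
      s01[u] = (stim[t] - 1) % 2;           // S1/S3 -> 0, S2/S4 -> 1
      ch[u] = resp[t] - 1;
      if (outc[t] == 3) re[u] = NA_REAL;
      else re[u] = (outc[t] == 1) ? 1.0 : -1.0;
      (void)reward_group;
    }
    return std::make_tuple(s01, ch, re);
  };

  const int nl = lr_grid.size(), nb = beta_grid.size();
  const int nrr = r0_rew_grid.size(), nrp = r0_pun_grid.size();

  IntegerVector s01r, chr, s01p, chp;
  NumericVector rer, rep_;
  std::tie(s01r, chr, rer) = build(rs, true);
  std::tie(s01p, chp, rep_) = build(ps, false);

  std::vector<double> A = group_table(s01r, chr, rer, lr_grid, beta_grid,
                                      r0_rew_grid);
  std::vector<double> B = group_table(s01p, chp, rep_, lr_grid, beta_grid,
                                      r0_pun_grid);

  const size_t nll = (size_t)nl * nl;
  // Enumerate the variant's free grid, invoking fn(i, j, b, r, p, negLLE).
  auto enumerate = [&](const std::function<void(int, int, int, int, int,
                                                double)>& fn) {
    for (int b = 0; b < nb; ++b) {
      for (int j = 0; j < nl; ++j) {
        for (int i = 0; i < nl; ++i) {
          if (variant == 5 && i != j) continue;
          const size_t base = (size_t)i + (size_t)nl * j;
          switch (variant) {
          case 1: // five_param: all (r, p)
            for (int r = 0; r < nrr; ++r) {
              const double a = A[base + nll * (b + (size_t)nb * r)];
              for (int p = 0; p < nrp; ++p) {
                fn(i, j, b, r, p, a + B[base + nll * (b + (size_t)nb * p)]);
              }
            }
            break;
          case 2: // r0_shared: r == p (grids must be identical)
            for (int r = 0; r < nrr; ++r) {
              fn(i, j, b, r, r,
                 A[base + nll * (b + (size_t)nb * r)] +
                 B[base + nll * (b + (size_t)nb * r)]);
            }
            break;
          case 3: // r0_inv: p mirrors r on a symmetric grid
            for (int r = 0; r < nrr; ++r) {
              const int p = nrp - 1 - r;
              fn(i, j, b, r, p,
                 A[base + nll * (b + (size_t)nb * r)] +
                 B[base + nll * (b + (size_t)nb * p)]);
            }
            break;
          default: // r0_zero / single_lr: single r0 value (grid length 1)
            fn(i, j, b, 0, 0, A[base + nll * b] + B[base + nll * b]);
            break;
          }
        }
      }
    }
  };

  // Pass 1: exact minimum.  Pass 2: all points within tol of it.
  double best = std::numeric_limits<double>::infinity();
  enumerate([&](int, int, int, int, int, double v) {
    if (v < best) best = v;
  });

  std::vector<int> ti, tj, tb, tr, tp; // 0-based tied indices
  bool truncated = false;
  long long n_ties = 0;
  enumerate([&](int i, int j, int b, int r, int p, double v) {
    if (v <= best + tol) {
      ++n_ties;
      if ((int)ti.size() < max_ties) {
        ti.push_back(i); tj.push_back(j); tb.push_back(b);
        tr.push_back(r); tp.push_back(p);
      } else {
        truncated = true;
      }
    }
  });

  const int m = ti.size();
  IntegerMatrix ties(m, 5);
  for (int u = 0; u < m; ++u) {
    ties(u, 0) = ti[u] + 1; ties(u, 1) = tj[u] + 1; ties(u, 2) = tb[u] + 1;
    ties(u, 3) = tr[u] + 1; ties(u, 4) = tp[u] + 1;
  }
  colnames(ties) = CharacterVector::create("lr_plus", "lr_minus", "beta",
                                           "r0_rew", "r0_pun");
  return List::create(_["negLLE"] = best, _["ties"] = ties,
                      _["n_ties"] = (double)n_ties,
                      _["truncated"] = truncated);
}
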