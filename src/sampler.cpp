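// Metropolis-Hastings-within-Gibbs core over a banded symmetric frequency
// matrix.  State is kept in log space (u = log t); the proposal is
// Gaussian in u with per-pixel scale, and the acceptance ratio carries the
// +u change-of-variable term for the log transform.
//
// Banded layout: matrices are n x (band+1); element (i, d) is the pair
// (i, i+d), 0-based.  Cells with i+d >= n are never touched.
//
// Reproducibility: each (chain, sweep, tile) triple gets its own
// counter-based RNG stream, so results depend only on the tile schedule's
// phase structure, not on how tiles within a phase are distributed over
// executors.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on (0, 1]
  double unif() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    double u1 = unif();
    double u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) *
           std::cos(6.283185307179586476925287 * u2);
  }
};

uint64_t mix_seed(uint64_t a, uint64_t b, uint64_t c, uint64_t d) {
  SplitMix s(a);
  s.s ^= s.next() + b;
  s.s ^= s.next() + c;
  s.s ^= s.next() + d;
  return s.next();
}

const int VAR_FULL = 0, VAR_UNIFORM = 1, VAR_GAUSS = 2, VAR_FIXED = 3;

struct Model {
  const NumericMatrix& o;
  const NumericVector& lb;      // per-bin log bias
  const NumericVector& lg;      // per-distance log expectation
  const NumericVector& omega2;  // per-distance local variance
  const NumericMatrix& sigma2;  // per-pixel smoothness variance
  const LogicalMatrix& eRow;    // pruned row transitions
  const LogicalMatrix& eCol;    // pruned column transitions
  const LogicalVector& maskbin; // usable bins
  int n, band, variant;
  double sigma2_fixed;

  bool valid(int i, int j) const {
    return i >= 0 && j < n && (j - i) <= band && maskbin[i] && maskbin[j];
  }

  bool pruned(int ai, int aj, int bi, int bj) const {
    if (bi < ai || (bi == ai && bj < aj)) {
      std::swap(ai, bi);
      std::swap(aj, bj);
    }
    int di = bi - ai, dj = bj - aj, ad = aj - ai;
    if (di == 0 && dj == 1) return eCol(ai, ad);
    if (di == 1 && dj == 0) return eRow(ai, ad);
    if (di == 1 && dj == 1) return eRow(ai, ad) || eCol(ai, ad);
    if (di == 1 && dj == -1) {
      int cd = (aj - 1) - (ai + 1);
      bool cc = (cd >= 0) ? (bool)eCol(ai + 1, cd) : false;
      return eRow(ai, ad) || cc;
    }
    return false;
  }

  // canonical deduplicated unmasked neighbours of (i, i+d)
  int collect_neighbors(int i, int d, int* qi, int* qd) const {
    static const int DI[8] = {-1, 1, 0, 0, -1, 1, -1, 1};
    static const int DJ[8] = {0, 0, -1, 1, -1, 1, 1, -1};
    int j = i + d, m = 0;
    for (int k = 0; k < 8; ++k) {
      int ai = i + DI[k], aj = j + DJ[k];
      if (ai > aj) std::swap(ai, aj);
      if (!valid(ai, aj)) continue;
      if (ai == i && aj == j) continue;
      bool dup = false;
      for (int r = 0; r < m; ++r) {
        if (qi[r] == ai && qd[r] == aj - ai) { dup = true; break; }
      }
      if (dup) continue;
      qi[m] = ai;
      qd[m] = aj - ai;
      ++m;
    }
    return m;
  }

  // unnormalised log conditional at u-value lt, without the lgamma(o+1)
  // constant (cancels in MH ratios)
  double cond(int i, int d, double lt, const NumericMatrix& u) const {
    int j = i + d;
    double lrate = lb[i] + lb[j] + lt;
    if (lrate > 700.0) return R_NegInf;
    double ll = o(i, d) * lrate - std::exp(lrate);
    if (variant != VAR_UNIFORM) {
      double dd = lt - lg[d];
      ll -= dd * dd / (2.0 * omega2[d]);
    }
    if (variant == VAR_FULL || variant == VAR_FIXED) {
      int qi[8], qd[8];
      int m = collect_neighbors(i, d, qi, qd);
      double s2p = sigma2(i, d);
      for (int r = 0; r < m; ++r) {
        if (pruned(i, j, qi[r], qi[r] + qd[r])) continue;
        double uq = u(qi[r], qd[r]);
        if (!R_finite(uq)) continue;
        double s2 = (variant == VAR_FIXED)
                        ? sigma2_fixed
                        : std::max(s2p, sigma2(qi[r], qd[r]));
        double dd = lt - uq;
        ll -= dd * dd / (2.0 * s2);
      }
    }
    return ll;
  }
};

}  // namespace

// One or more full sweeps over the band, tile-scheduled, with optional
// periodic proposal adaptation (Robbins-Monro gain gain0 / round).
// Mutates u, sd, acc_int, prop_int in place; returns bookkeeping.
// [[Rcpp::export]]
List cpp_run_chunk(NumericMatrix u, NumericMatrix sd,
                   NumericMatrix acc_int, NumericMatrix prop_int,
                   NumericMatrix o, NumericVector lb, NumericVector lg,
                   NumericVector omega2, NumericMatrix sigma2,
                   LogicalMatrix eRow, LogicalMatrix eCol,
                   LogicalVector maskbin, int variant, double sigma2_fixed,
                   int n_sweeps, int sweep0, bool adapt, int adapt_interval,
                   double target, double gain0, int round0,
                   IntegerVector tile_start, IntegerVector tile_end,
                   IntegerVector tile_order, double seed, int chain_id) {
  int n = u.nrow(), band = u.ncol() - 1;
  Model mod{o,    lb,   lg,      omega2, sigma2,      eRow, eCol,
            maskbin, n, band, variant, sigma2_fixed};
  double acc_tot = 0.0, prop_tot = 0.0;
  int round_no = round0;

  for (int s = 0; s < n_sweeps; ++s) {
    int sweep = sweep0 + s;
    for (int ot = 0; ot < tile_order.size(); ++ot) {
      int tl = tile_order[ot];
      SplitMix rng(mix_seed((uint64_t)seed, (uint64_t)chain_id,
                            (uint64_t)sweep, (uint64_t)tl));
      for (int i = tile_start[tl]; i < tile_end[tl]; ++i) {
        if (!maskbin[i]) continue;
        int dmax = std::min(band, n - 1 - i);
        for (int d = 0; d <= dmax; ++d) {
          if (!maskbin[i + d]) continue;
          double lt = u(i, d);
          double prop = lt + sd(i, d) * rng.norm();
          double la = mod.cond(i, d, prop, u) - mod.cond(i, d, lt, u) +
                      (prop - lt);
          prop_int(i, d) += 1;
          prop_tot += 1;
          if (la >= 0.0 || std::log(rng.unif()) < la) {
            u(i, d) = prop;
            acc_int(i, d) += 1;
            acc_tot += 1;
          }
        }
      }
    }
    if (adapt && ((sweep + 1) % adapt_interval == 0)) {
      ++round_no;
      double gain = gain0 / round_no;
      for (int i = 0; i < n; ++i) {
        int dmax = std::min(band, n - 1 - i);
        for (int d = 0; d <= dmax; ++d) {
          double p = prop_int(i, d);
          if (p > 0) {
            double rate = acc_int(i, d) / p;
            double f = std::exp(gain * (rate - target));
            double v = sd(i, d) * f;
            sd(i, d) = std::min(std::max(v, 1e-6), 1e3);
          }
          acc_int(i, d) = 0;
          prop_int(i, d) = 0;
        }
      }
    }
  }
  return List::create(_["accepted"] = acc_tot, _["proposed"] = prop_tot,
                      _["round"] = round_no,
                      _["sweep_end"] = sweep0 + n_sweeps);
}

// Log conditional for one pixel/candidate, for cross-checking the compiled
// path against the R reference (omits the lgamma(o+1) constant).
// [[Rcpp::export]]
double cpp_log_conditional(double tval, int i, int d, NumericMatrix u,
                           NumericMatrix o, NumericVector lb,
                           NumericVector lg, NumericVector omega2,
                           NumericMatrix sigma2, LogicalMatrix eRow,
                           LogicalMatrix eCol, LogicalVector maskbin,
                           int variant, double sigma2_fixed) {
  int n = u.nrow(), band = u.ncol() - 1;
  Model mod{o,    lb,   lg,      omega2, sigma2,      eRow, eCol,
            maskbin, n, band, variant, sigma2_fixed};
  if (tval <= 0) return R_NegInf;
  return mod.cond(i, d, std::log(tval), u);
}

// Single-pixel MH chain with fixed neighbours: the conditional has the
// same Poisson + local + pairwise shape, with the neighbour log-values and
// edge variances supplied directly.  Returns thinned draws of u.
// [[Rcpp::export]]
NumericVector cpp_single_pixel_chain(double o, double lb, double lg,
                                     double omega2, NumericVector nbr_u,
                                     NumericVector nbr_s2, int variant,
                                     int n_draws, int thin, double sd,
                                     double u0, double seed) {
  SplitMix rng(mix_seed((uint64_t)seed, 7u, 11u, 13u));
  int nn = nbr_u.size();
  auto cond = [&](double lt) {
    double lrate = lb + lt;
    if (lrate > 700.0) return R_NegInf;
    double ll = o * lrate - std::exp(lrate);
    if (variant != VAR_UNIFORM) {
      double dd = lt - lg;
      ll -= dd * dd / (2.0 * omega2);
    }
    if (variant == VAR_FULL || variant == VAR_FIXED) {
      for (int r = 0; r < nn; ++r) {
        double dd = lt - nbr_u[r];
        ll -= dd * dd / (2.0 * nbr_s2[r]);
      }
    }
    return ll;
  };
  NumericVector out(n_draws);
  double lt = u0;
  double cur = cond(lt);
  for (int s = 0; s < n_draws; ++s) {
    for (int k = 0; k < thin; ++k) {
      double prop = lt + sd * rng.norm();
      double cp = cond(prop);
      double la = cp - cur + (prop - lt);
      if (la >= 0.0 || std::log(rng.unif()) < la) {
        lt = prop;
        cur = cp;
      }
    }
    out[s] = lt;
  }
  return out;
}
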