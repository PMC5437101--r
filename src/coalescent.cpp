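// Monte Carlo structured coalescent: expected branch lengths subtending
// (i, j) sampled leaves under a piecewise demographic timeline.
//
// Time runs backward from the present in units of 2*Na generations.
// Pair-coalescence rate in deme d at backward time u is 1/nu_d(u);
// per-lineage backward migration rate out of deme d is M_d/2 (M scaled as
// 2*Na*m). Time-varying sizes are handled by thinning against a per-epoch
// rate bound computed from the epoch's extreme sizes.
//
// A lineage's (i, j) class is fixed over its lifetime, so branch length is
// accrued lazily: each lineage stores its birth time and contributes
// (death - birth) to its class when it coalesces; the root contributes to
// the always-masked (n1, n2) corner and is skipped.
//
// Epochs arrive PRESENT -> PAST, one row each:
//   col 0: duration (Inf allowed only for the final, constant, 1-deme row)
//   col 1: ndemes (1 or 2)
//   col 2-4: deme0 size fn: type (0 const, 1 linear, 2 exp), ancient, recent
//   col 5-7: deme1 size fn (ignored when ndemes == 1)
//   col 8: M for deme0 lineages (backward rate M/2 each)
//   col 9: M for deme1 lineages
#include <Rcpp.h>
using namespace Rcpp;

static inline double size_at(int type, double anc, double rec,
                             double dur, double u) {
  // u = backward time from the epoch's recent edge; forward s = dur - u
  if (type == 0) return anc;
  double f = (dur - u) / dur;
  if (type == 1) return anc + (rec - anc) * f;
  return anc * std::pow(rec / anc, f); // exponential
}

// [[Rcpp::export]]
List sfs_mc_engine(NumericMatrix epochs, int n1, int n2, int reps) {
  const int E = epochs.nrow();
  const int ncell = (n1 + 1) * (n2 + 1);
  std::vector<double> tsum(ncell, 0.0), tsq(ncell, 0.0), tloc(ncell);
  std::vector<int> li(n1 + n2), lj(n1 + n2), ld(n1 + n2);
  std::vector<double> tb(n1 + n2); // lineage birth times (global)

  for (int r = 0; r < reps; ++r) {
    std::fill(tloc.begin(), tloc.end(), 0.0);
    int k = n1 + n2;
    int nd0 = (int)epochs(0, 1);
    int k0 = 0;
    for (int x = 0; x < n1; ++x) { li[x] = 1; lj[x] = 0; ld[x] = 0; tb[x] = 0.0; }
    for (int x = 0; x < n2; ++x) {
      li[n1 + x] = 0; lj[n1 + x] = 1;
      ld[n1 + x] = (nd0 == 2) ? 1 : 0;
      tb[n1 + x] = 0.0;
    }
    k0 = (nd0 == 2) ? n1 : n1 + n2;
    double gt = 0.0; // global elapsed scaled time

    for (int e = 0; e < E && k > 1; ++e) {
      const double dur = epochs(e, 0);
      const int nd = (int)epochs(e, 1);
      if (nd == 1 && k0 < k) {
        for (int x = 0; x < k; ++x) ld[x] = 0;
        k0 = k;
      }
      const int t0 = (int)epochs(e, 2);
      const double a0 = epochs(e, 3), r0 = epochs(e, 4);
      const int t1 = (int)epochs(e, 5);
      const double a1 = epochs(e, 6), r1 = epochs(e, 7);
      const double mig0 = epochs(e, 8) / 2.0, mig1 = epochs(e, 9) / 2.0;
      const double min0 = std::min(a0, r0);
      const double min1 = (nd == 2) ? std::min(a1, r1) : 1.0;

      double u = 0.0;
      while (k > 1) {
        int k1 = k - k0;
        double bound = 0.5 * k0 * (k0 - 1) / min0;
        if (nd == 2)
          bound += 0.5 * k1 * (k1 - 1) / min1 + k0 * mig0 + k1 * mig1;
        if (bound <= 0.0) { // isolated single lineages cannot meet this epoch
          if (!std::isfinite(dur))
            stop("timeline never coalesces remaining lineages");
          gt += dur - u;
          u = dur;
          break;
        }
        double t = exp_rand() / bound;
        if (u + t >= dur) {
          gt += dur - u;
          break;
        }
        u += t;
        gt += t;
        double nu0 = size_at(t0, a0, r0, dur, u);
        double c0 = 0.5 * k0 * (k0 - 1) / nu0;
        double c1 = 0.0, m0 = 0.0, m1 = 0.0;
        if (nd == 2) {
          double nu1 = size_at(t1, a1, r1, dur, u);
          c1 = 0.5 * k1 * (k1 - 1) / nu1;
          m0 = k0 * mig0; m1 = k1 * mig1;
        }
        double total = c0 + c1 + m0 + m1;
        if (total > bound * (1.0 + 1e-9))
          stop("instantaneous event rate exceeds the thinning bound");
        double v = unif_rand() * bound;
        if (v >= total) continue; // thinned
        if (v < c0 + c1) {
          // coalescence in deme dsel: choose an unordered pair uniformly
          int dsel = (v < c0) ? 0 : 1;
          int kd = (dsel == 0) ? k0 : k1;
          int p1 = (int)(unif_rand() * kd); if (p1 >= kd) p1 = kd - 1;
          int p2 = (int)(unif_rand() * (kd - 1)); if (p2 >= kd - 1) p2 = kd - 2;
          if (p2 >= p1) ++p2;
          int a = -1, b = -1, seen = 0;
          for (int x = 0; x < k; ++x) if (ld[x] == dsel) {
            if (seen == p1) a = x;
            if (seen == p2) b = x;
            ++seen;
          }
          tloc[li[a] + lj[a] * (n1 + 1)] += gt - tb[a];
          tloc[li[b] + lj[b] * (n1 + 1)] += gt - tb[b];
          li[a] += li[b]; lj[a] += lj[b]; tb[a] = gt;
          li[b] = li[k - 1]; lj[b] = lj[k - 1]; ld[b] = ld[k - 1];
          tb[b] = tb[k - 1];
          --k;
          if (dsel == 0) --k0;
        } else {
          int dsel = (v < c0 + c1 + m0) ? 0 : 1;
          int kd = (dsel == 0) ? k0 : k1;
          int p1 = (int)(unif_rand() * kd); if (p1 >= kd) p1 = kd - 1;
          int seen = 0;
          for (int x = 0; x < k; ++x) if (ld[x] == dsel) {
            if (seen == p1) { ld[x] = 1 - dsel; break; }
            ++seen;
          }
          if (dsel == 0) --k0; else ++k0;
        }
      }
    }
    // surviving non-root lineages never occur (k == 1 here unless the
    // timeline errored); the root's class is the masked corner
    for (int c = 0; c < ncell; ++c) {
      tsum[c] += tloc[c];
      tsq[c] += tloc[c] * tloc[c];
    }
  }

  NumericMatrix mean(n1 + 1, n2 + 1), se(n1 + 1, n2 + 1);
  for (int c = 0; c < ncell; ++c) {
    double m = tsum[c] / reps;
    mean[c] = m;
    double var = tsq[c] / reps - m * m;
    if (var < 0) var = 0;
    se[c] = std::sqrt(var / reps);
  }
  return List::create(_["mean"] = mean, _["se"] = se);
}
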