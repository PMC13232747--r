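// Compiled simulation engine.
//
// Mirrors the pure-R reference engine in R/dynamics.R draw for draw: the
// RNG consumption order (event kind -> actor -> placement -> overflow) and
// the floating-point accumulation (long double for payoff sums and
// cumulative weights, matching R's sum()/cumsum() internals) are identical,
// so both engines produce bit-identical trajectories from the same seed.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// One uniform draw -> index in 0..k-1 (floor inversion; matches runif_index).
static inline int unif_index0(int k) {
  double u = unif_rand();
  int idx = (int)std::floor(u * (double)k);
  if (idx >= k) idx = k - 1;
  if (idx < 0) idx = 0;
  return idx;
}

// [[Rcpp::export]]
List sim_run_cpp(IntegerMatrix counts0, NumericMatrix A,
                 double beta, double lambda, double q,
                 int n_cap, int n_events, int sample_every,
                 bool global_selection, bool removal_excludes_offspring) {
  const int d = counts0.nrow();
  const int m = counts0.ncol();
  IntegerMatrix counts = clone(counts0);

  std::vector<int> gsize(m, 0);
  for (int g = 0; g < m; ++g)
    for (int t = 0; t < d; ++t) gsize[g] += counts(t, g);

  long long ev_imm = 0, ev_rep = 0, ev_split = 0, ev_cull = 0;

  std::vector<int> snap_clocks;
  std::vector<IntegerMatrix> snaps;
  snap_clocks.push_back(0);
  snaps.push_back(clone(counts));

  std::vector<double> w;   w.reserve((size_t)d * m);
  std::vector<int> wg, wt; wg.reserve((size_t)d * m); wt.reserve((size_t)d * m);
  std::vector<int> present; present.reserve(d);
  std::vector<int> types;  types.reserve(n_cap + 1);
  std::vector<char> toA(n_cap + 1);
  std::vector<int> cA(d), cB(d);

  for (int ev = 1; ev <= n_events; ++ev) {
    int g_aff;
    double u1 = unif_rand();
    if (u1 < lambda) {
      // immigration: uniform type, then uniform target group
      int t = unif_index0(d);
      int g = unif_index0(m);
      counts(t, g) += 1;
      gsize[g] += 1;
      g_aff = g;
      ++ev_imm;
    } else {
      ++ev_rep;
      int g_sel, t_sel;
      if (global_selection) {
        // weights over all (group, type) pairs, group-major, type ascending
        w.clear(); wg.clear(); wt.clear();
        for (int g = 0; g < m; ++g) {
          int Ng = gsize[g];
          present.clear();
          for (int t = 0; t < d; ++t) if (counts(t, g) > 0) present.push_back(t);
          for (size_t a = 0; a < present.size(); ++a) {
            int j = present[a];
            long double acc = 0.0L;
            for (size_t b = 0; b < present.size(); ++b) {
              int k = present[b];
              acc += A(j, k) * (double)counts(k, g);
            }
            double s = (double)acc;
            double pi = (Ng >= 2) ? (s - A(j, j)) / (double)(Ng - 1) : 0.0;
            double f = std::exp(beta * pi);
            w.push_back((double)counts(j, g) * f);
            wg.push_back(g);
            wt.push_back(j);
          }
        }
        long double c = 0.0L;
        std::vector<double> cw(w.size());
        for (size_t i = 0; i < w.size(); ++i) { c += w[i]; cw[i] = (double)c; }
        double total = cw.back();
        double target = unif_rand() * total;
        size_t idx = 0;
        while (idx + 1 < cw.size() && cw[idx] < target) ++idx;
        g_sel = wg[idx];
        t_sel = wt[idx];
      } else {
        // uniform group, then within-group replication probability b_j
        int g = unif_index0(m);
        int Ng = gsize[g];
        present.clear();
        for (int t = 0; t < d; ++t) if (counts(t, g) > 0) present.push_back(t);
        std::vector<double> cw(present.size());
        long double c = 0.0L;
        for (size_t a = 0; a < present.size(); ++a) {
          int j = present[a];
          long double acc = 0.0L;
          for (size_t b = 0; b < present.size(); ++b) {
            int k = present[b];
            acc += A(j, k) * (double)counts(k, g);
          }
          double s = (double)acc;
          double pi = (Ng >= 2) ? (s - A(j, j)) / (double)(Ng - 1) : 0.0;
          double f = std::exp(beta * pi);
          c += (double)counts(j, g) * f;
          cw[a] = (double)c;
        }
        double total = cw.back();
        double target = unif_rand() * total;
        size_t idx = 0;
        while (idx + 1 < cw.size() && cw[idx] < target) ++idx;
        g_sel = g;
        t_sel = present[idx];
      }
      counts(t_sel, g_sel) += 1;
      gsize[g_sel] += 1;
      g_aff = g_sel;
    }

    if (gsize[g_aff] > n_cap) {
      double us = unif_rand();
      bool do_split = (m > 1) && (us < q);
      if (do_split) {
        ++ev_split;
        int Nsz = gsize[g_aff];
        types.clear();
        for (int t = 0; t < d; ++t)
          for (int cidx = 0; cidx < counts(t, g_aff); ++cidx) types.push_back(t);
        int nA;
        do {
          nA = 0;
          for (int i = 0; i < Nsz; ++i) {
            toA[i] = (unif_rand() < 0.5) ? 1 : 0;
            nA += toA[i];
          }
        } while (nA < 2 || (Nsz - nA) < 2);
        std::fill(cA.begin(), cA.end(), 0);
        std::fill(cB.begin(), cB.end(), 0);
        for (int i = 0; i < Nsz; ++i) {
          if (toA[i]) cA[types[i]] += 1; else cB[types[i]] += 1;
        }
        if (removal_excludes_offspring) {
          // remove one of the m-1 groups other than the parent slot
          int k = unif_index0(m - 1);
          int slot = (k < g_aff) ? k : k + 1;
          for (int t = 0; t < d; ++t) {
            counts(t, g_aff) = cA[t];
            counts(t, slot) = cB[t];
          }
          gsize[g_aff] = nA;
          gsize[slot] = Nsz - nA;
        } else {
          // candidates: the m-1 other groups (ascending), then offspring A, B
          int k = unif_index0(m + 1);
          if (k <= m - 2) {
            int slot = (k < g_aff) ? k : k + 1;
            for (int t = 0; t < d; ++t) {
              counts(t, g_aff) = cA[t];
              counts(t, slot) = cB[t];
            }
            gsize[g_aff] = nA;
            gsize[slot] = Nsz - nA;
          } else if (k == m - 1) {
            // offspring A removed, B takes the parent slot
            for (int t = 0; t < d; ++t) counts(t, g_aff) = cB[t];
            gsize[g_aff] = Nsz - nA;
          } else {
            // offspring B removed, A takes the parent slot
            for (int t = 0; t < d; ++t) counts(t, g_aff) = cA[t];
            gsize[g_aff] = nA;
          }
        }
      } else {
        ++ev_cull;
        int Nsz = gsize[g_aff];
        int idx = unif_index0(Nsz);  // uniform individual, ascending type order
        int cum = 0, t = 0;
        for (t = 0; t < d; ++t) {
          cum += counts(t, g_aff);
          if (idx < cum) break;
        }
        counts(t, g_aff) -= 1;
        gsize[g_aff] -= 1;
      }
    }

    if (ev % sample_every == 0) {
      snap_clocks.push_back(ev);
      snaps.push_back(clone(counts));
    }
  }

  if (snap_clocks.back() != n_events) {
    snap_clocks.push_back(n_events);
    snaps.push_back(clone(counts));
  }

  List snapshots(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) snapshots[i] = snaps[i];

  return List::create(
    _["clocks"] = wrap(snap_clocks),
    _["snapshots"] = snapshots,
    _["counters"] = IntegerVector::create((int)ev_imm, (int)ev_rep,
                                          (int)ev_split, (int)ev_cull));
}
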