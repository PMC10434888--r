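#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo engine for donation-game death-birth dynamics on a growing
// network.  Nodes are pre-sorted by first activation so the active set of
// snapshot l is a prefix; the caller passes the CSR adjacency of the final
// network and per-node activation snapshots in that sorted order.
//
// process = 1: every snapshot runs to absorption (all-D ends the run,
//              all-C advances with newcomers entering as defectors).
// process = 2: snapshots 1..L-1 run exactly g updates (early exit on
//              absorption); the final snapshot runs to absorption.
//
// One update: pick an active individual i uniformly; i copies an active
// neighbour j with probability (1 + delta * u_j) * w_ij, normalized, where
// u_j is j's edge-weighted average payoff on the current snapshot.
// Uses R's RNG: results are reproducible under set.seed().

// [[Rcpp::export(name = ".sim_engine")]]
List sim_engine(int n, IntegerVector ptr, IntegerVector nbr, NumericVector wgt,
                IntegerVector first_active, IntegerVector snap_sizes,
                double b, double c, double delta,
                int process, double g, int n_runs, double max_steps) {
  const int L = snap_sizes.size();
  std::vector<int> x(n);
  std::vector<double> prob(n), upay(n);
  long long n_fix = 0;
  double steps_C = 0.0, steps_D = 0.0, steps_all = 0.0;

  for (int run = 0; run < n_runs; ++run) {
    std::fill(x.begin(), x.end(), 0);
    int m1 = snap_sizes[0];
    int seed_node = (int)(unif_rand() * m1);
    if (seed_node >= m1) seed_node = m1 - 1;
    x[seed_node] = 1;
    int coop = 1;
    double steps = 0.0;
    bool dead = false;

    for (int l = 0; l < L && !dead; ++l) {
      int n_act = snap_sizes[l];
      bool to_absorption = (process == 1) || (l == L - 1);
      double budget = to_absorption ? R_PosInf : g;
      double done = 0.0;
      while (coop > 0 && coop < n_act && done < budget) {
        if (steps >= max_steps)
          stop("run exceeded the step-count safety cap (%g)", max_steps);
        // choose the updating individual
        int i = (int)(unif_rand() * n_act);
        if (i >= n_act) i = n_act - 1;
        // copy probabilities over active neighbours of i
        double tot = 0.0;
        int kk = 0;
        for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
          int j = nbr[e];
          if (first_active[j] > l + 1) continue;
          double fw;
          if (delta == 0.0) {
            fw = wgt[e];
          } else {
            // payoff of j on the current snapshot
            double num = 0.0, den = 0.0;
            for (int e2 = ptr[j]; e2 < ptr[j + 1]; ++e2) {
              int k = nbr[e2];
              if (first_active[k] > l + 1) continue;
              den += wgt[e2];
              num += wgt[e2] * x[k];
            }
            double uj = -c * x[j] + b * num / den;
            double fj = 1.0 + delta * uj;
            if (fj <= 0.0)
              stop("non-positive fitness encountered; reduce delta");
            fw = fj * wgt[e];
          }
          prob[kk] = tot += fw;
          upay[kk] = j;  // reuse buffer to hold the neighbour id
          ++kk;
        }
        // kk > 0 is guaranteed: snapshots are connected
        double r = unif_rand() * tot;
        int pick = 0;
        while (pick < kk - 1 && prob[pick] < r) ++pick;
        int j = (int)upay[pick];
        coop += x[j] - x[i];
        x[i] = x[j];
        steps += 1.0;
        done += 1.0;
      }
      if (coop == 0) dead = true;
    }

    bool fixated = (!dead) && (coop == n);
    if (fixated) { ++n_fix; steps_C += steps; }
    else steps_D += steps;
    steps_all += steps;
  }

  return List::create(
    _["n_fix"] = (double)n_fix,
    _["t_C"] = n_fix > 0 ? steps_C / n_fix : NA_REAL,
    _["t_D"] = (n_runs - n_fix) > 0 ? steps_D / (n_runs - n_fix) : NA_REAL,
    _["t_all"] = steps_all / n_runs);
}
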