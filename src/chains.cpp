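#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time Markov simulation of poly-glutamate chain dynamics on RpsF.
// Per step one of {add, cut, release, idle} occurs with fixed probabilities.
// Cleavage is a no-op at or below the minimal length (RimB floor); reaching
// max_len terminates the chain (mass accumulates at the cap). Uses R's RNG so
// set.seed() gives reproducible trajectories.

// [[Rcpp::export]]
IntegerVector simulate_chains_cpp(int n_sims, int horizon, double p_add,
                                  double p_cut, double release_prob,
                                  int min_cut, int max_len, int init_len) {
  IntegerVector out(n_sims);
  const double t_add = p_add;
  const double t_cut = p_add + p_cut;
  const double t_rel = p_add + p_cut + release_prob;
  for (int i = 0; i < n_sims; ++i) {
    int len = init_len;
    for (int step = 0; step < horizon; ++step) {
      if (len >= max_len) break;
      double u = unif_rand();
      if (u < t_add) {
        ++len;
      } else if (u < t_cut) {
        if (len > min_cut) --len;
      } else if (u < t_rel) {
        break;
      }
    }
    out[i] = len;
  }
  return out;
}

// Cell-population simulation: n_rpsf chains share one RimABK complex and a
// finite glutamate pool (pool < 0 means unlimited). The complex binds one
// chain and extends it processively, unbinding with release_prob; cleavage
// events hit a uniformly chosen chain and return the cut glutamate to the
// pool. Conservation (sum of lengths + pool == initial pool) is checked at
// every event.

// [[Rcpp::export]]
List simulate_population_cpp(int n_rpsf, double horizon, double p_add,
                             double p_cut, double release_prob, int min_cut,
                             int max_len, double pool, int n_snapshots) {
  IntegerVector lengths(n_rpsf);
  const bool finite_pool = pool >= 0;
  const double pool0 = pool;
  long long incorporated = 0;
  int bound = -1;
  const double t_add = p_add;
  const double t_cut = p_add + p_cut;
  const double t_rel = p_add + p_cut + release_prob;
  long long n_events = (long long)horizon;
  long long snap_every = n_snapshots > 0 ? std::max((long long)1, n_events / n_snapshots)
                                         : n_events + 1;
  std::vector<double> snap_step, snap_incorp, snap_pool;
  bool conserved = true;

  for (long long ev = 0; ev < n_events; ++ev) {
    double u = unif_rand();
    if (u < t_add) {
      if (bound < 0) bound = (int)(unif_rand() * n_rpsf) % n_rpsf;
      if (lengths[bound] < max_len && (!finite_pool || pool >= 1.0)) {
        ++lengths[bound];
        ++incorporated;
        if (finite_pool) pool -= 1.0;
      }
    } else if (u < t_cut) {
      int j = (int)(unif_rand() * n_rpsf) % n_rpsf;
      if (lengths[j] > min_cut) {
        --lengths[j];
        --incorporated;
        if (finite_pool) pool += 1.0;
      }
    } else if (u < t_rel) {
      bound = -1;
    }
    if (finite_pool && incorporated + (long long)pool != (long long)pool0)
      conserved = false;
    if ((ev + 1) % snap_every == 0) {
      snap_step.push_back((double)(ev + 1));
      snap_incorp.push_back((double)incorporated);
      snap_pool.push_back(finite_pool ? pool : R_PosInf);
    }
  }

  return List::create(
      _["lengths"] = lengths,
      _["pool_remaining"] = finite_pool ? pool : R_PosInf,
      _["conserved"] = conserved,
      _["snap_step"] = snap_step,
      _["snap_incorporated"] = snap_incorp,
      _["snap_pool"] = snap_pool);
}
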