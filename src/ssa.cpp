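// Gillespie direct-method core.  Propensities are falling-factorial mass
// action with an optional tabulated multiplier indexed by one state
// variable (used for rational-QSS propensities of reduced models).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List ssa_direct_cpp(IntegerVector init,
                    IntegerMatrix reactants,   // nrxn x nspec multiplicities
                    IntegerMatrix net,         // nrxn x nspec net changes
                    NumericVector rate,
                    IntegerVector table_var,   // 1-based species index or 0
                    List tables,               // per reaction: numeric vector or NULL
                    NumericVector grid,        // sorted, >= 0
                    double t_end,
                    double max_events,
                    bool record_events) {
  const int nspec = init.size();
  const int nrxn = rate.size();
  std::vector<long long> x(nspec);
  for (int i = 0; i < nspec; ++i) x[i] = init[i];

  const int ng = grid.size();
  NumericMatrix states(ng, nspec);
  std::vector<double> ev_t;
  std::vector<long long> ev_x;

  std::vector<NumericVector> tabs(nrxn);
  for (int j = 0; j < nrxn; ++j)
    if (table_var[j] > 0) tabs[j] = as<NumericVector>(tables[j]);

  double t = 0.0;
  double n_events = 0.0;
  int gi = 0;
  int status = 0;          // 0 ok, 1 absorbing, 2 table range, 3 neg propensity
  bool truncated = false;
  std::vector<double> a(nrxn);

  auto record_up_to = [&](double tnext) {
    while (gi < ng && grid[gi] < tnext) {
      for (int i = 0; i < nspec; ++i) states(gi, i) = (double) x[i];
      ++gi;
    }
  };

  while (t < t_end) {
    double a0 = 0.0;
    for (int j = 0; j < nrxn; ++j) {
      double p = rate[j];
      for (int i = 0; i < nspec; ++i) {
        int m = reactants(j, i);
        for (int l = 0; l < m; ++l) p *= (double)(x[i] - l);
        if (m > 0 && x[i] < m) p = 0.0;
      }
      if (table_var[j] > 0 && p != 0.0) {
        long long idx = x[table_var[j] - 1];
        if (idx < 0 || idx >= tabs[j].size()) { status = 2; goto done; }
        p *= tabs[j][idx];
      }
      if (p < 0.0) { status = 3; goto done; }
      a[j] = p;
      a0 += p;
    }
    if (a0 <= 0.0) { status = 1; break; }   // absorbing state
    {
      double dt = R::exp_rand() / a0;
      double tnext = t + dt;
      if (tnext > t_end) { t = t_end; break; }
      record_up_to(tnext);
      double u = unif_rand() * a0;
      int j = 0;
      double acc = a[0];
      while (j < nrxn - 1 && u > acc) { ++j; acc += a[j]; }
      for (int i = 0; i < nspec; ++i) x[i] += net(j, i);
      t = tnext;
      n_events += 1.0;
      if (record_events) {
        if ((double) ev_t.size() < max_events) {
          ev_t.push_back(t);
          for (int i = 0; i < nspec; ++i) ev_x.push_back(x[i]);
        } else truncated = true;
      }
      if (n_events >= max_events) { truncated = true; break; }
    }
  }
done:
  // fill the remaining grid with the final (or absorbing) state
  while (gi < ng) {
    for (int i = 0; i < nspec; ++i) states(gi, i) = (double) x[i];
    ++gi;
  }
  IntegerVector xf(nspec);
  for (int i = 0; i < nspec; ++i) xf[i] = (int) x[i];
  List out = List::create(
    _["states"] = states,
    _["final_state"] = xf,
    _["t_final"] = t,
    _["n_events"] = n_events,
    _["status"] = status,
    _["truncated"] = truncated);
  if (record_events) {
    int ne = ev_t.size();
    NumericVector et(ne);
    NumericMatrix ex(ne, nspec);
    for (int k = 0; k < ne; ++k) {
      et[k] = ev_t[k];
      for (int i = 0; i < nspec; ++i) ex(k, i) = (double) ev_x[k * nspec + i];
    }
    out["event_times"] = et;
    out["event_states"] = ex;
  }
  return out;
}
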