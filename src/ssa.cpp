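#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) of a mass-action
// reaction network. Propensities use combinatorial counting: a reactant with
// stoichiometry r contributes x(x-1)...(x-r+1) and the per-reaction
// multiplier supplies any 1/2 factors, so e.g. dimerization B+B -> B2 with
// multiplier 1/2 has a = k * B(B-1)/2.
//
// Between events the state is piecewise constant; dwell-time-weighted first
// and second moments of every species, and of the persistence ratio
// R = num/(num + den) with num = sum(w_num * x) (free toxin) and
// den = sum(w_den * x) (free antitoxin), are accumulated over
// [burn_in, t_end] so downstream statistics are exact regardless of how the
// trajectory is stored (full event resolution or a uniform grid).
//
// Uses R's RNG (unif_rand / exp_rand) so set.seed() controls reproducibility.

static inline double falling(double x, int r) {
  double v = 1.0;
  for (int i = 0; i < r; ++i) v *= (x - i);
  return v > 0.0 ? v : 0.0;
}

// [[Rcpp::export]]
List ssa_run_cpp(IntegerMatrix reactant, IntegerMatrix net, NumericVector k,
                 NumericVector mult, NumericVector init,
                 double t_end, double burn_in,
                 bool record_events, int max_store, int n_grid,
                 NumericVector w_num, NumericVector w_den, double threshold) {
  const int nS = init.size();
  const int nR = k.size();
  std::vector<double> x(init.begin(), init.end());

  // sparse reactant / net stoichiometry
  std::vector<std::vector<int>> r_idx(nR), r_ord(nR), n_idx(nR);
  std::vector<std::vector<double>> n_chg(nR);
  for (int j = 0; j < nR; ++j)
    for (int i = 0; i < nS; ++i) {
      if (reactant(i, j) > 0) { r_idx[j].push_back(i); r_ord[j].push_back(reactant(i, j)); }
      if (net(i, j) != 0)     { n_idx[j].push_back(i); n_chg[j].push_back(net(i, j)); }
    }

  // sparse R-statistic weights
  bool track_r = w_num.size() == nS && w_den.size() == nS;
  std::vector<int> num_i, den_i;
  std::vector<double> num_w, den_w;
  if (track_r) {
    for (int i = 0; i < nS; ++i) {
      if (w_num[i] != 0.0) { num_i.push_back(i); num_w.push_back(w_num[i]); }
      if (w_den[i] != 0.0) { den_i.push_back(i); den_w.push_back(w_den[i]); }
    }
    track_r = !num_i.empty() && !den_i.empty();
  }
  auto r_value = [&](bool &defined) {
    double num = 0.0, den = 0.0;
    for (size_t q = 0; q < num_i.size(); ++q) num += num_w[q] * x[num_i[q]];
    for (size_t q = 0; q < den_i.size(); ++q) den += den_w[q] * x[den_i[q]];
    defined = num + den > 0.0;
    return defined ? num / (num + den) : NA_REAL;
  };

  std::vector<double> a(nR);
  auto propensity = [&](int j) {
    double v = mult[j] * k[j];
    for (size_t q = 0; q < r_idx[j].size(); ++q)
      v *= falling(x[r_idx[j][q]], r_ord[j][q]);
    return v;
  };

  // storage
  int cap = record_events ? max_store : (n_grid + 1);
  std::vector<double> st_t; st_t.reserve(std::min(cap, 1 << 20));
  std::vector<double> st_x; st_x.reserve((size_t)std::min(cap, 1 << 20) * nS);
  bool truncated = false;
  double grid_dt = t_end / n_grid;
  int next_grid = 0;
  auto store = [&](double t) {
    st_t.push_back(t);
    for (int i = 0; i < nS; ++i) st_x.push_back(x[i]);
  };
  if (record_events) store(0.0);

  // accumulators over [burn_in, t_end]
  std::vector<double> sx(nS, 0.0), sx2(nS, 0.0);
  double r_def = 0.0, r_sum = 0.0, r_sum2 = 0.0, r_above = 0.0;
  int r_up = 0;
  int prev_side = -1;  // -1 unknown/undefined, 0 below-or-equal, 1 above
  double t = 0.0;
  long long n_events = 0;
  bool absorbed = false;

  RNGScope scope;
  while (t < t_end) {
    double a0 = 0.0;
    for (int j = 0; j < nR; ++j) { a[j] = propensity(j); a0 += a[j]; }
    double t_next;
    int jfire = -1;
    if (a0 <= 0.0) {
      t_next = t_end;
      absorbed = true;
    } else {
      t_next = t + exp_rand() / a0;
      if (t_next > t_end) t_next = t_end;
      else {
        double u = unif_rand() * a0, c = 0.0;
        for (int j = 0; j < nR; ++j) { c += a[j]; if (u <= c) { jfire = j; break; } }
        if (jfire < 0) jfire = nR - 1;
      }
    }

    // dwell of current state over [t, t_next], clipped to [burn_in, t_end]
    double lo = t > burn_in ? t : burn_in;
    double hi = t_next < t_end ? t_next : t_end;
    if (hi > lo) {
      double w = hi - lo;
      for (int i = 0; i < nS; ++i) { sx[i] += w * x[i]; sx2[i] += w * x[i] * x[i]; }
      if (track_r) {
        bool defined;
        double R = r_value(defined);
        if (defined) {
          r_def += w; r_sum += w * R; r_sum2 += w * R * R;
          int side = R > threshold ? 1 : 0;
          if (side == 1) r_above += w;
          if (side == 1 && prev_side == 0) ++r_up;
          prev_side = side;
        }
      }
    } else if (track_r && hi <= lo && t < burn_in) {
      // still in burn-in: track the side so the first post-burn-in crossing
      // is not spuriously counted
      bool defined;
      double R = r_value(defined);
      if (defined) prev_side = R > threshold ? 1 : 0;
    }

    // grid recording uses the state that held over [t, t_next)
    if (!record_events) {
      while (next_grid <= n_grid && next_grid * grid_dt < t_next) {
        store(next_grid * grid_dt);
        ++next_grid;
      }
    }

    if (absorbed || jfire < 0) { t = t_next; if (t >= t_end) break; continue; }

    for (size_t q = 0; q < n_idx[jfire].size(); ++q)
      x[n_idx[jfire][q]] += n_chg[jfire][q];
    ++n_events;
    t = t_next;
    if (record_events) {
      if ((int)st_t.size() < max_store) store(t);
      else truncated = true;
    }
    if (n_events % 1048576 == 0) Rcpp::checkUserInterrupt();
  }
  if (!record_events) {
    while (next_grid <= n_grid) { store(next_grid * grid_dt); ++next_grid; }
  }

  int n_stored = st_t.size();
  NumericVector times(st_t.begin(), st_t.end());
  NumericMatrix states(n_stored, nS);
  for (int r = 0; r < n_stored; ++r)
    for (int i = 0; i < nS; ++i) states(r, i) = st_x[(size_t)r * nS + i];

  double T = t_end - burn_in;
  return List::create(
    _["times"] = times, _["states"] = states,
    _["n_events"] = (double)n_events, _["absorbed"] = absorbed,
    _["truncated_store"] = truncated,
    _["final_state"] = NumericVector(x.begin(), x.end()),
    _["acc"] = List::create(
      _["T"] = T,
      _["sum_x"] = NumericVector(sx.begin(), sx.end()),
      _["sum_x2"] = NumericVector(sx2.begin(), sx2.end()),
      _["r_time_defined"] = r_def, _["r_sum"] = r_sum, _["r_sum2"] = r_sum2,
      _["r_time_above"] = r_above, _["r_upcrossings"] = r_up));
}
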