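#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven simulation of one image presentation (present + rest) for
// the two-layer WTA network.  State lives in the R environment `net` and
// is updated in place; synaptic-operation counters are accumulated into
// the `ledger` environment stored in `net`.
//
// Per-step event order: conductance decay -> spike delivery (input spikes
// of this step, lateral spikes of the previous step) -> Euler membrane
// update and spike detection -> trace decay -> depression for pre spikes
// -> potentiation for post spikes (pre-reset y2) -> trace resets.
//
// Conductances and traces decay by exact exponential factors.  The
// presynaptic trace x_j is evaluated lazily: it is always reset to 1 at a
// spike and decays purely exponentially, so its value at step t is
// exp((last_spike_step - t) * dt / tau_x).
//
// phase: 0 = train, 1 = assign, 2 = infer.  STDP counters are only
// touched when `plastic` is true.
// [[Rcpp::export]]
List sim_present_cpp(Environment net, NumericVector p_spike,
                     int n_present, int n_rest, double dt,
                     List exc_par, List inh_par, List plas,
                     double w_exc_inh, double w_inh_exc,
                     bool plastic, bool adapt_theta, int phase,
                     double norm_total) {
  NumericMatrix w_m = net["w"];
  IntegerMatrix status_m = net["status"];
  NumericVector v_e_v = net["v_exc"], ge_v = net["ge_exc"],
                gi_v = net["gi_exc"], theta_v = net["theta"],
                ref_e_v = net["refrac_exc"], v_i_v = net["v_inh"],
                ge_i_v = net["ge_inh"], ref_i_v = net["refrac_inh"],
                x_v = net["x"], y1_v = net["y1"], y2_v = net["y2"];
  IntegerVector prev_e_v = net["prev_exc"], prev_i_v = net["prev_inh"];
  Environment ledger = net["ledger"];

  const int n_in = w_m.nrow(), n_exc = w_m.ncol();
  if (p_spike.size() != n_in) stop("p_spike length must equal n_input");

  double* w = w_m.begin();
  int* status = status_m.begin();
  double *v_e = v_e_v.begin(), *ge = ge_v.begin(), *gi = gi_v.begin(),
         *theta = theta_v.begin(), *ref_e = ref_e_v.begin(),
         *v_i = v_i_v.begin(), *ge_i = ge_i_v.begin(),
         *ref_i = ref_i_v.begin(), *x = x_v.begin(), *y1 = y1_v.begin(),
         *y2 = y2_v.begin();
  int *prev_e = prev_e_v.begin(), *prev_i = prev_i_v.begin();

  const double tau_m = exc_par["tau_m"], v_r = exc_par["v_r"],
               v_th = exc_par["v_th"], E_exc = exc_par["E_exc"],
               E_inh = exc_par["E_inh"], tau_ge = exc_par["tau_ge"],
               tau_gi = exc_par["tau_gi"],
               tau_th = exc_par["tau_theta"], t_ref = exc_par["t_refrac"];
  const double th_plus = adapt_theta ? (double) exc_par["theta_plus"] : 0.0;
  const double i_tau_m = inh_par["tau_m"], i_v_r = inh_par["v_r"],
               i_v_th = inh_par["v_th"], i_E_exc = inh_par["E_exc"],
               i_tau_ge = inh_par["tau_ge"], i_t_ref = inh_par["t_refrac"];
  const double tau_x = plas["tau_x"], tau_y1 = plas["tau_y1"],
               tau_y2 = plas["tau_y2"], mu_pre = plas["mu_pre"],
               mu_post = plas["mu_post"], w_max = plas["w_max"];

  const double fge = std::exp(-dt / tau_ge), fgi = std::exp(-dt / tau_gi),
               fge_i = std::exp(-dt / i_tau_ge),
               fy1 = std::exp(-dt / tau_y1), fy2 = std::exp(-dt / tau_y2),
               fth = adapt_theta ? std::exp(-dt / tau_th) : 1.0;
  const double dt_over_taum = dt / tau_m, i_dt_over_taum = dt / i_tau_m;
  const double dt_over_taux = dt / tau_x;

  // status is constant within one image (pruning acts between images)
  std::vector<int> row_nonrem(n_in, 0), row_act(n_in, 0), col_act(n_exc, 0);
  for (int i = 0; i < n_exc; ++i) {
    const int* sc = status + (size_t) i * n_in;
    for (int j = 0; j < n_in; ++j) {
      if (sc[j] != 2) row_nonrem[j]++;
      if (sc[j] == 0) { row_act[j]++; col_act[i]++; }
    }
  }

  // Lazy presynaptic trace: x_j at step t equals
  // exp((last_x[j] - t) * dt / tau_x).  A carried-in value x0 is treated
  // as the state after the previous image's final decay, so it sees one
  // decay before first use at step 0 (last = log(x0)/D - 1).
  std::vector<double> last_x(n_in);
  for (int j = 0; j < n_in; ++j)
    last_x[j] = x[j] > 0 ? std::log(x[j]) / dt_over_taux - 1.0 : -1e18;

  // Pre-draw input spike times: Bernoulli(p) per step realized by
  // geometric gap sampling (identical distribution, far fewer draws).
  std::vector<int> sp_step, sp_unit;  // time-sorted via counting pass
  std::vector<int> step_count(n_present + 1, 0);
  {
    std::vector<int> tmp_step, tmp_unit;
    for (int j = 0; j < n_in; ++j) {
      double p = p_spike[j];
      if (p <= 0) continue;
      if (p >= 1.0) {
        for (int s = 0; s < n_present; ++s) {
          tmp_step.push_back(s); tmp_unit.push_back(j);
        }
        continue;
      }
      double l1p = std::log1p(-p);
      int t = -1;
      for (;;) {
        double u = unif_rand();
        int gap = 1 + (int) std::floor(std::log(u) / l1p);
        if (gap < 1) gap = 1;
        t += gap;
        if (t >= n_present) break;
        tmp_step.push_back(t);
        tmp_unit.push_back(j);
      }
    }
    // counting sort by step so delivery walks spikes in time order
    for (size_t k = 0; k < tmp_step.size(); ++k) step_count[tmp_step[k] + 1]++;
    for (int s = 0; s < n_present; ++s) step_count[s + 1] += step_count[s];
    sp_step.resize(tmp_step.size());
    sp_unit.resize(tmp_step.size());
    std::vector<int> pos(step_count.begin(), step_count.end() - 1);
    for (size_t k = 0; k < tmp_step.size(); ++k) {
      sp_unit[pos[tmp_step[k]]++] = tmp_unit[k];
    }
  }
  const double n_input_spikes = (double) sp_unit.size();

  IntegerVector counts(n_exc);
  double acc = 0, stdp_pre = 0, stdp_post = 0, lat_ei = 0, lat_ie = 0;
  double ndw = 0, sdw = 0, sdw2 = 0;
  std::vector<int> fired_e(n_exc, 0), fired_i(n_exc, 0);
  const int n_steps = n_present + n_rest;

  for (int t = 0; t < n_steps; ++t) {
    const bool present = t < n_present;
    const int s0 = present ? step_count[t] : 0;
    const int s1 = present ? step_count[t + 1] : 0;
    for (int i = 0; i < n_exc; ++i) {
      ge[i] *= fge; gi[i] *= fgi; ge_i[i] *= fge_i;
    }
    for (int k = s0; k < s1; ++k) {
      const int j = sp_unit[k];
      const double* wj = w + j;
      const int* sj = status + j;
      for (int i = 0; i < n_exc; ++i)
        if (sj[(size_t) i * n_in] != 2) ge[i] += wj[(size_t) i * n_in];
      acc += row_nonrem[j];
    }
    for (int i = 0; i < n_exc; ++i) {
      if (prev_e[i]) { ge_i[i] += w_exc_inh; lat_ei += 1; }
      if (prev_i[i]) {
        for (int k = 0; k < n_exc; ++k)
          if (k != i) gi[k] += w_inh_exc;
        lat_ie += n_exc - 1;
      }
    }
    int any_fired = 0;
    for (int i = 0; i < n_exc; ++i) {
      bool can = true;
      if (ref_e[i] > 0) { ref_e[i] -= dt; can = false; }
      else {
        v_e[i] += ((v_r - v_e[i]) - ge[i] * (v_e[i] - E_exc) -
                   gi[i] * (v_e[i] - E_inh)) * dt_over_taum;
      }
      theta[i] *= fth;
      int f = (can && v_e[i] >= v_th + theta[i]) ? 1 : 0;
      if (f) {
        v_e[i] = v_r;
        theta[i] += th_plus;
        ref_e[i] = t_ref;
        counts[i]++;
        any_fired = 1;
      }
      fired_e[i] = f;
    }
    for (int i = 0; i < n_exc; ++i) {
      bool can = true;
      if (ref_i[i] > 0) { ref_i[i] -= dt; can = false; }
      else {
        v_i[i] += ((i_v_r - v_i[i]) - ge_i[i] * (v_i[i] - i_E_exc)) *
                  i_dt_over_taum;
      }
      int f = (can && v_i[i] >= i_v_th) ? 1 : 0;
      if (f) { v_i[i] = i_v_r; ref_i[i] = i_t_ref; }
      fired_i[i] = f;
    }
    if (plastic) {
      for (int i = 0; i < n_exc; ++i) { y1[i] *= fy1; y2[i] *= fy2; }
      for (int k = s0; k < s1; ++k) {
        const int j = sp_unit[k];
        double* wj = w + j;
        const int* sj = status + j;
        for (int i = 0; i < n_exc; ++i) {
          if (sj[(size_t) i * n_in] == 0) {
            double old = wj[(size_t) i * n_in];
            double nw = old - mu_pre * y1[i];
            if (nw < 0) nw = 0;
            double d = nw - old;
            wj[(size_t) i * n_in] = nw;
            sdw += d; sdw2 += d * d;
          }
        }
        stdp_pre += row_act[j];
        ndw += row_act[j];
      }
      if (any_fired) {
        for (int i = 0; i < n_exc; ++i) {
          if (fired_e[i]) {
            const double y2i = y2[i];
            double* wc = w + (size_t) i * n_in;
            const int* sc = status + (size_t) i * n_in;
            for (int j = 0; j < n_in; ++j) {
              if (sc[j] == 0) {
                double xj = last_x[j] > -1e17 ?
                  std::exp((last_x[j] - t) * dt_over_taux) : 0.0;
                double old = wc[j];
                double nw = old + mu_post * xj * y2i;
                if (nw > w_max) nw = w_max;
                double d = nw - old;
                wc[j] = nw;
                sdw += d; sdw2 += d * d;
              }
            }
            stdp_post += col_act[i];
            ndw += col_act[i];
          }
        }
      }
      for (int k = s0; k < s1; ++k) last_x[sp_unit[k]] = t;
      if (any_fired)
        for (int i = 0; i < n_exc; ++i)
          if (fired_e[i]) { y1[i] = 1.0; y2[i] = 1.0; }
    }
    for (int i = 0; i < n_exc; ++i) {
      prev_e[i] = fired_e[i];
      prev_i[i] = fired_i[i];
    }
  }

  // homeostatic divisive normalization of each neuron's active input
  // weights to a fixed total; frozen/removed synapses are never touched
  if (plastic && norm_total > 0) {
    for (int i = 0; i < n_exc; ++i) {
      double* wc = w + (size_t) i * n_in;
      const int* sc = status + (size_t) i * n_in;
      double s = 0;
      for (int j = 0; j < n_in; ++j)
        if (sc[j] == 0) s += wc[j];
      if (s > 0) {
        const double scale = norm_total / s;
        for (int j = 0; j < n_in; ++j)
          if (sc[j] == 0) {
            double nw = wc[j] * scale;
            wc[j] = nw > w_max ? w_max : nw;
          }
      }
    }
  }

  if (plastic)  // persist the lazily evaluated presynaptic traces
    for (int j = 0; j < n_in; ++j)
      x[j] = last_x[j] > -1e17 ?
        std::exp((last_x[j] - (n_steps - 1)) * dt_over_taux) : 0.0;

  for (int i = 0; i < n_exc; ++i)
    if (!R_finite(v_e[i]) || !R_finite(ge[i]) || !R_finite(gi[i]) ||
        !R_finite(theta[i]))
      stop("sim_present_cpp: non-finite neuron state");

  const char* suffix = phase == 0 ? "train" : (phase == 1 ? "assign" : "infer");
  std::string acc_name = std::string(suffix) + "_accum";
  ledger[acc_name] = as<double>(ledger[acc_name]) + acc;
  ledger[std::string("lateral_ei_") + suffix] =
      as<double>(ledger[std::string("lateral_ei_") + suffix]) + lat_ei;
  ledger[std::string("lateral_ie_") + suffix] =
      as<double>(ledger[std::string("lateral_ie_") + suffix]) + lat_ie;
  ledger[std::string("images_") + suffix] =
      as<double>(ledger[std::string("images_") + suffix]) + 1;
  if (plastic) {
    ledger["train_stdp_pre"] = as<double>(ledger["train_stdp_pre"]) + stdp_pre;
    ledger["train_stdp_post"] =
        as<double>(ledger["train_stdp_post"]) + stdp_post;
  }

  return List::create(_["counts"] = counts,
                      _["n_input_spikes"] = n_input_spikes,
                      _["dw_n"] = ndw, _["dw_sum"] = sdw,
                      _["dw_sumsq"] = sdw2);
}
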