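// Fast engine for the dentate gyrus epileptogenesis simulator.
//
// One call runs the whole schedule: per-iteration membrane integration,
// stochastic firing, NSE/NSI Euler steps, Hebb/anti-Hebb coincidence
// accounting, and the per-morphogenetic-step compensation-theory rewiring
// with deterministic synapse formation. The control flow and RNG call
// order (one runif(n) block for the initial firing state, then one per
// iteration) mirror the pure-R reference engine, so small runs can be
// cross-checked between the two.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <set>
using namespace Rcpp;

static inline double sigmoid(double x) {
  // matches stats::plogis branching
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// [[Rcpp::export]]
List dg_sim_cpp(NumericMatrix C0, NumericMatrix Wbase,
                IntegerVector class_code, NumericVector theta,
                NumericVector kappa, NumericVector vm_smooth,
                double nu, double rho, double eta, double eta_anti,
                bool hebb_on_inhibitory,
                double rest_lo, double rest_hi, double L, double p_rest,
                double dt, int ipm, int n_steps,
                NumericVector k_offer_exc, NumericVector k_offer_inh,
                NumericVector k_offer_pre,
                double ct_gain, double ct_margin, double free_decay,
                double prune_exc, NumericVector prune_inh,
                NumericVector prune_out,
                double a_e, double b_e, double tau_e,
                double a_i, double tau_i, double g_e, double g_i,
                double alpha, int stim_start_iter, int stim_len,
                IntegerVector inverted, double phi_bar,
                double t_i_days, double t_f_days, bool inversion_on,
                IntegerMatrix gmap, LogicalVector frozen9,
                IntegerVector snap_steps, bool record_neurons) {
  const int n = C0.nrow();
  NumericMatrix C = clone(C0);
  NumericMatrix EW(n, n);
  NumericMatrix Nh(n, n), Dbuf(n, n), dct(n, n);
  std::vector<double> Fpost(n, 0.0);  // post-firing counts; Na = F - Nh

  std::vector<bool> cellular(n), exc_pre(n), is_gc(n), is_mc(n);
  std::vector<int> ina_idx;
  for (int i = 0; i < n; ++i) {
    cellular[i] = class_code[i] <= 2;
    exc_pre[i] = class_code[i] <= 2;
    is_gc[i] = class_code[i] == 1;
    is_mc[i] = class_code[i] == 2;
    if (class_code[i] == 3) ina_idx.push_back(i);
  }
  std::vector<int> inv_idx;
  for (int k = 0; k < inverted.size(); ++k) inv_idx.push_back(inverted[k] - 1);
  std::vector<bool> is_inv(n, false);
  for (size_t k = 0; k < inv_idx.size(); ++k) is_inv[inv_idx[k]] = true;

  bool any_frozen = false;
  for (int g = 0; g < 9; ++g) if (frozen9[g]) any_frozen = true;
  // frozen pair predicate via gmap codes (0 on the diagonal)
  auto frozen_at = [&](int i, int j) {
    int g = gmap(i, j);
    return g > 0 && frozen9[g - 1];
  };

  // per-group pair counts for the rate means
  std::vector<double> gcount(9, 0.0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (gmap(i, j) > 0) gcount[gmap(i, j) - 1] += 1.0;

  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      EW(i, j) = Wbase(i, j) * C(i, j);

  std::set<int> snaps(snap_steps.begin(), snap_steps.end());
  std::vector<NumericMatrix> snap_mats;
  std::vector<std::string> snap_names;

  // state
  std::vector<int> z(n), z_new(n);
  std::vector<double> s(n, p_rest), nse(n, 0.0), nsi(n, 0.0);
  std::vector<double> prob(n), vm(n), prob_acc(n, 0.0), vm_ema(n);
  std::vector<bool> ema_init(n, false);
  std::vector<double> fe(n, 0.0), fi(n, 0.0), fp(n, 0.0);
  std::vector<int> act_now;
  act_now.reserve(n);

  {
    NumericVector u = runif(n);
    for (int i = 0; i < n; ++i) z[i] = u[i] < p_rest ? 1 : 0;
  }

  // outputs
  NumericVector mean_s_gc(n_steps), mean_s_gc_inv(n_steps),
      mean_s_mc(n_steps), mean_s_in(n_steps), mean_nse(n_steps),
      mean_nsi(n_steps);
  NumericVector nse_iter((long)n_steps * ipm), nsi_iter((long)n_steps * ipm);
  int n_cellular = 0;
  for (int i = 0; i < n; ++i) if (cellular[i]) ++n_cellular;
  NumericMatrix group_mean(n_steps, 9), r_ct(n_steps, 9),
      r_hebb(n_steps, 9), r_anti(n_steps, 9);
  NumericMatrix s_mat, nse_mat, nsi_mat;
  if (record_neurons) {
    s_mat = NumericMatrix(n_steps, n);
    nse_mat = NumericMatrix(n_steps, n);
    nsi_mat = NumericMatrix(n_steps, n);
  }

  const long T_total = (long)n_steps * ipm;
  for (long t = 1; t <= T_total; ++t) {
    double time_days = (double)(t - 1) * dt / 1440.0;

    if (inversion_on) {
      double ph = phi_bar * (std::tanh((time_days - t_i_days) / 0.2) + 1.0) *
                  (std::tanh((t_f_days - time_days) / 1.5) + 1.0);
      double gw = ph - phi_bar;
      for (size_t a = 0; a < inv_idx.size(); ++a)
        for (size_t b = 0; b < ina_idx.size(); ++b)
          EW(inv_idx[a], ina_idx[b]) = gw * C(inv_idx[a], ina_idx[b]);
    }

    double alpha_t = (stim_len > 0 && t >= stim_start_iter &&
                      t < stim_start_iter + (long)stim_len)
                         ? alpha : 0.0;
    for (int i = 0; i < n; ++i) {
      double nsv = cellular[i] ? g_e * nse[i] - g_i * nsi[i] : 0.0;
      vm[i] = nsv + alpha_t;
    }
    for (int j = 0; j < n; ++j) {
      if (!z[j]) continue;
      for (int i = 0; i < n; ++i) vm[i] += EW(i, j);
    }
    for (int i = 0; i < n; ++i) {
      if (!ema_init[i]) { vm_ema[i] = vm[i]; ema_init[i] = true; }
      else vm_ema[i] += vm_smooth[i] * (vm[i] - vm_ema[i]);
      prob[i] = sigmoid((vm_ema[i] - theta[i]) / kappa[i]);
    }

    for (int i = 0; i < n; ++i) z_new[i] = unif_rand() < prob[i] ? 1 : 0;
    for (int i = 0; i < n; ++i) prob_acc[i] += prob[i];
    {
      act_now.clear();
      for (int i = 0; i < n; ++i)
        if (z_new[i]) { act_now.push_back(i); Fpost[i] += 1.0; }
      for (int j = 0; j < n; ++j) {
        if (!z[j]) continue;
        for (size_t a = 0; a < act_now.size(); ++a)
          Nh(act_now[a], j) += 1.0;
      }
    }

    // NSE/NSI Euler step from pre-update values
    for (int i = 0; i < n; ++i) {
      if (!cellular[i]) continue;
      bool active = nse[i] > 0 || s[i] > L;
      double sup = s[i] - L; if (sup < 0) sup = 0;
      double d_e = a_e * sup + (active ? b_e * nse[i] : 0.0) - nse[i] / tau_e;
      double d_i = a_i * nse[i] - nsi[i] / tau_i;
      nse[i] += dt * d_e; if (nse[i] < 0) nse[i] = 0;
      nsi[i] += dt * d_i; if (nsi[i] < 0) nsi[i] = 0;
    }
    for (int i = 0; i < n; ++i) z[i] = z_new[i];

    {
      double me = 0, mi = 0;
      for (int i = 0; i < n; ++i)
        if (cellular[i]) { me += nse[i]; mi += nsi[i]; }
      nse_iter[t - 1] = me / n_cellular;
      nsi_iter[t - 1] = mi / n_cellular;
    }

    if (t % ipm != 0) continue;

    // ---- morphogenetic step ----
    int k = (int)(t / ipm);  // 1-based step index
    for (int i = 0; i < n; ++i) { s[i] = prob_acc[i] / ipm; prob_acc[i] = 0; }

    std::vector<double> d_high(n), d_low(n), r_high(n), r_low(n),
        r_low_inh(n), r_low_out(n), released(n, 0.0);
    for (int i = 0; i < n; ++i) {
      double hi = rest_hi + ct_margin, lo = rest_lo - ct_margin;
      d_high[i] = s[i] > hi ? ct_gain * (s[i] - hi) : 0.0;
      d_low[i] = s[i] < lo ? ct_gain * (lo - s[i]) : 0.0;
      r_high[i] = std::min(nu * d_high[i] * prune_exc, 1.0);
      r_low_inh[i] = std::min(nu * d_low[i] * prune_inh[i], 1.0);
      r_low_out[i] = std::min(nu * d_low[i] * prune_out[i], 1.0);
      r_low[i] = std::min(nu * d_low[i], 1.0);
    }
    // free elements retract if they fail to bind
    for (int i = 0; i < n; ++i) {
      fe[i] *= 1.0 - free_decay;
      fi[i] *= 1.0 - free_decay;
      fp[i] *= 1.0 - free_decay;
    }

    // compensation: removals (rows: inputs of i; cols: outputs of j)
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i) {
        if (i == j) { dct(i, j) = 0; continue; }
        if (any_frozen && frozen_at(i, j)) { dct(i, j) = 0; continue; }
        double c = C(i, j), d = 0.0;
        if (exc_pre[j] && r_high[i] > 0) {
          double rem = r_high[i] * c;
          d -= rem;
          released[i] += rem;
        }
        if (!exc_pre[j] && r_low_inh[i] > 0) d -= r_low_inh[i] * c;
        double ro = exc_pre[j] ? r_low_out[j] : r_low_inh[j];
        if (ro > 0) d -= ro * c;
        dct(i, j) = d;
      }
    }
    for (int i = 0; i < n; ++i) {
      fe[i] += released[i] + nu * d_low[i] * k_offer_exc[i];
      fi[i] += nu * d_high[i] * k_offer_inh[i];
      fp[i] = fp[i] * (1.0 - r_low[i]) + nu * d_high[i] * k_offer_pre[i];
    }

    // deterministic synapse formation: excitatory then inhibitory market
    for (int market = 0; market < 2; ++market) {
      bool want_exc = market == 0;
      double sum_a = 0, sum_b = 0;
      for (int j = 0; j < n; ++j)
        if (exc_pre[j] == want_exc) sum_a += fp[j];
      for (int i = 0; i < n; ++i) sum_b += (want_exc ? fe[i] : fi[i]);
      double M = std::min(sum_a, sum_b);
      if (M <= 0) continue;
      double Z = 0;
      for (int j = 0; j < n; ++j) {
        double aj = (exc_pre[j] == want_exc) ? fp[j] : 0.0;
        for (int i = 0; i < n; ++i) {
          double o = (i == j || aj == 0) ? 0.0
                     : (want_exc ? fe[i] : fi[i]) * aj;
          if (o != 0 && any_frozen && frozen_at(i, j)) o = 0;
          Dbuf(i, j) = o;
          Z += o;
        }
      }
      if (Z <= 0) continue;
      std::vector<double> rs(n, 0.0), cs(n, 0.0);
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i) {
          double d = M * Dbuf(i, j) / Z;
          Dbuf(i, j) = d;
          rs[i] += d;
          cs[j] += d;
        }
      double scale = 1.0;
      for (int i = 0; i < n; ++i) {
        double b = want_exc ? fe[i] : fi[i];
        if (rs[i] > 0 && b / rs[i] < scale) scale = b / rs[i];
      }
      for (int j = 0; j < n; ++j) {
        double aj = (exc_pre[j] == want_exc) ? fp[j] : 0.0;
        if (cs[j] > 0 && aj / cs[j] < scale) scale = aj / cs[j];
      }
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i) {
          double d = Dbuf(i, j) * scale;
          if (d == 0) continue;
          dct(i, j) += d;
        }
      for (int i = 0; i < n; ++i) {
        if (want_exc) fe[i] -= rs[i] * scale; else fi[i] -= rs[i] * scale;
        fp[i] -= cs[i] * scale;
      }
    }
    for (int i = 0; i < n; ++i) {
      if (fe[i] < 0) fe[i] = 0;
      if (fi[i] < 0) fi[i] = 0;
      if (fp[i] < 0) fp[i] = 0;
    }

    // Hebb / anti-Hebb, apply all rules, clip at zero, record rates
    std::vector<double> sum_ct(9, 0.0), sum_h(9, 0.0), sum_a9(9, 0.0),
        sum_c(9, 0.0);
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i) {
        int g = gmap(i, j);
        if (g == 0) continue;
        bool froz = any_frozen && frozen_at(i, j);
        bool plastic = !froz && (hebb_on_inhibitory || exc_pre[j]);
        double dh = plastic ? rho * eta * C(i, j) * Nh(i, j) : 0.0;
        double da = plastic
            ? -rho * eta_anti * C(i, j) * (Fpost[i] - Nh(i, j)) : 0.0;
        double cn = C(i, j) + dct(i, j) + dh + da;
        if (cn < 0) cn = 0;
        C(i, j) = cn;
        sum_ct[g - 1] += dct(i, j);
        sum_h[g - 1] += dh;
        sum_a9[g - 1] += da;
        sum_c[g - 1] += cn;
        Nh(i, j) = 0;
      }
    }
    for (int g = 0; g < 9; ++g) {
      group_mean(k - 1, g) = sum_c[g] / gcount[g];
      r_ct(k - 1, g) = sum_ct[g] / gcount[g];
      r_hebb(k - 1, g) = sum_h[g] / gcount[g];
      r_anti(k - 1, g) = sum_a9[g] / gcount[g];
    }
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        EW(i, j) = Wbase(i, j) * C(i, j);
    std::fill(Fpost.begin(), Fpost.end(), 0.0);

    // population summaries
    double sg = 0, sgi = 0, sm = 0, si = 0, me = 0, mi = 0;
    int ng = 0, ngi = 0, nm = 0, ni = 0, nc = 0;
    for (int i = 0; i < n; ++i) {
      if (is_gc[i]) { sg += s[i]; ++ng; }
      if (is_inv[i]) { sgi += s[i]; ++ngi; }
      if (is_mc[i]) { sm += s[i]; ++nm; }
      if (!cellular[i]) { si += s[i]; ++ni; }
      if (cellular[i]) { me += nse[i]; mi += nsi[i]; ++nc; }
    }
    mean_s_gc[k - 1] = sg / ng;
    mean_s_gc_inv[k - 1] = ngi > 0 ? sgi / ngi : NA_REAL;
    mean_s_mc[k - 1] = sm / nm;
    mean_s_in[k - 1] = si / ni;
    mean_nse[k - 1] = me / nc;
    mean_nsi[k - 1] = mi / nc;
    if (record_neurons) {
      for (int i = 0; i < n; ++i) {
        s_mat(k - 1, i) = s[i];
        nse_mat(k - 1, i) = nse[i];
        nsi_mat(k - 1, i) = nsi[i];
      }
    }
    if (snaps.count(k)) {
      snap_mats.push_back(clone(C));
      snap_names.push_back(std::to_string(k));
    }
  }

  List snapshots(snap_mats.size());
  for (size_t q = 0; q < snap_mats.size(); ++q) snapshots[q] = snap_mats[q];
  snapshots.names() = wrap(snap_names);
  List pools = List::create(
      Named("free_exc_post") = NumericVector(fe.begin(), fe.end()),
      Named("free_inh_post") = NumericVector(fi.begin(), fi.end()),
      Named("free_pre") = NumericVector(fp.begin(), fp.end()));
  List out = List::create(
      Named("mean_s_gc") = mean_s_gc, Named("mean_s_gc_inv") = mean_s_gc_inv,
      Named("mean_s_mc") = mean_s_mc, Named("mean_s_in") = mean_s_in,
      Named("mean_nse") = mean_nse, Named("mean_nsi") = mean_nsi,
      Named("group_mean") = group_mean, Named("r_ct") = r_ct,
      Named("r_hebb") = r_hebb, Named("r_anti") = r_anti,
      Named("snapshots") = snapshots, Named("C_final") = C,
      Named("pools") = pools, Named("nse_iter") = nse_iter,
      Named("nsi_iter") = nsi_iter);
  if (record_neurons) {
    out["s_mat"] = s_mat;
    out["nse_mat"] = nse_mat;
    out["nsi_mat"] = nsi_mat;
  }
  return out;
}
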