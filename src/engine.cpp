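// Closed-loop session engine: recurrent Izhikevich network surrogate for the
// cultured network, spike-bin efferent decoder, first-order plant surrogate
// and SA/RA Izhikevich encoder, advanced together on a 1 kHz control tick
// with 0.5 ms Euler substeps. The exported R operations implement the same
// update rules standalone; cross-checks live in the test suite.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Izhikevich encoder driven by a per-tick current series; returns 1-based
// tick indices at which the neuron spiked (at most one per tick).
// [[Rcpp::export]]
IntegerVector cpp_encode_stream(NumericVector I, double v0, double u0,
                                double a, double b, double c, double d,
                                double X, double Y, double Z,
                                double dt, int substeps) {
  std::vector<int> out;
  double v = v0, u = u0;
  const int n = I.size();
  for (int t = 0; t < n; ++t) {
    bool spiked = false;
    for (int s = 0; s < substeps; ++s) {
      double vo = v;
      v += dt * (X * vo * vo + Y * vo + Z + I[t] - u);
      u += dt * a * (b * vo - u);
      if (!std::isfinite(v) || std::fabs(v) > 1e6)
        stop("numerical instability in Izhikevich integration at dt = %f ms", dt);
      if (v >= 30.0) {
        v = c;
        u += d;
        spiked = true;
      }
    }
    if (spiked) out.push_back(t + 1);
  }
  return wrap(out);
}

// [[Rcpp::export]]
List cpp_run_session(
    int n_ticks, int warmup_ticks, int substeps, double dt,
    
    NumericVector na, NumericVector nb, NumericVector nc, NumericVector nd,
    NumericVector v0, NumericVector u0, NumericVector noise_sd,
    LogicalVector is_exc,
    
    IntegerVector pre_ptr, IntegerVector post_idx, NumericVector w,
    
    double U_dep, double tau_rec, double slow_inc, double tau_slow,
    double tau_syn,
    
    LogicalVector is_efferent, NumericVector stim_coupling,
    double stim_amp, int stim_dur_ticks,
    double stim_dep_u, double stim_dep_tau, double stim_adapt,
    double stim_adapt_rise,
    
    int efferent_mode,          
    bool deliver_stim, bool run_encoder,
    IntegerVector external_stim_ticks,   
    
    int bin_ticks, int s_thres, int ttl_ticks,
    
    double theta1, double theta2, double theta_c, double tau_ms,
    double release_tau_ms, double deadband,
    double stiffness, double force_noise_sd, int smooth_n,
    
    int enc_mode,               
    double enc_alpha, double enc_beta, double k_sa, double k_ra,
    double e_a, double e_b, double e_c, double e_d,
    double e_X, double e_Y, double e_Z,
    
    int es_period_ticks) {

  const int n = na.size();
  const double tick_ms = substeps * dt;
  const double tick_s = tick_ms / 1000.0;
  const double alpha_plant = std::exp(-tick_ms / tau_ms);
  const double alpha_release = std::exp(-tick_ms / release_tau_ms);
  const double g_decay = std::exp(-tick_ms / tau_slow);
  const double x_rec = tick_ms / tau_rec;

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> x(n, 1.0);       // synaptic resource per presyn neuron
  std::vector<double> g(n, 0.0);       // slow adaptation current
  std::vector<double> syn(n, 0.0);     // exponentially decaying synaptic current
  const double syn_decay = std::exp(-dt / tau_syn);

  std::vector<int> spike_neuron;
  std::vector<double> spike_ms;
  std::vector<int> enc_ticks, stim_ticks, ttl_onsets;
  NumericVector theta_series(n_ticks), fdc_series(n_ticks), fac_series(n_ticks);
  IntegerVector eff_counts(n_ticks);

  // external stimulation lookup
  std::vector<bool> ext_stim(n_ticks, false);
  for (int k = 0; k < external_stim_ticks.size(); ++k) {
    int t = external_stim_ticks[k];
    if (t >= 0 && t < n_ticks) ext_stim[t] = true;
  }

  // decoder state
  int bin_count = 0;
  long ttl_until = -1;   // last tick (0-based, inclusive) of the active pulse
  long next_allowed = 0; // earliest tick a new pulse may start

  // plant state
  double theta = theta1;
  double theta_eff = theta1;   // backlash-filtered angle seen by the sensor
  double fs_prev1 = 0.0, fs_prev2 = 0.0;
  std::vector<double> raw_ring(std::max(smooth_n, 1), 0.0);
  int raw_pos = 0;
  double raw_sum = 0.0;

  // encoder state (resting point of the default polynomial)
  double ev = -70.0, eu = e_b * -70.0;
  {
    double disc = (e_Y - e_b) * (e_Y - e_b) - 4.0 * e_X * e_Z;
    if (disc >= 0) {
      ev = (-(e_Y - e_b) - std::sqrt(disc)) / (2.0 * e_X);
      eu = e_b * ev;
    }
  }

  long stim_active_until = -1; // inclusive tick of ongoing stimulation current
  bool stim_pending = false;   // encoder spike last tick -> deliver this tick

  // settling period: run the network without recording so the session does
  // not start from an artificially synchronized state
  for (int t = 0; t < warmup_ticks; ++t) {
    for (int s = 0; s < substeps; ++s) {
      for (int i = 0; i < n; ++i) syn[i] *= syn_decay;
      for (int i = 0; i < n; ++i) {
        double I = noise_sd[i] * norm_rand() + syn[i] - g[i];
        double vo = v[i];
        double vn = vo + dt * (0.04 * vo * vo + 5.0 * vo + 140.0 + I - u[i]);
        u[i] += dt * na[i] * (nb[i] * vo - u[i]);
        if (vn >= 30.0) {
          v[i] = nc[i];
          u[i] += nd[i];
          g[i] += slow_inc;
          double res = is_exc[i] ? x[i] : 1.0;
          for (int k = pre_ptr[i]; k < pre_ptr[i + 1]; ++k)
            syn[post_idx[k]] += w[k] * res;
          if (is_exc[i]) x[i] -= U_dep * x[i];
        } else {
          v[i] = vn;
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      x[i] += (1.0 - x[i]) * x_rec;
      g[i] *= g_decay;
    }
  }
  double r_stim = 1.0;         // stimulation-pathway release resource
  double q_stim = 0.0;         // accumulated stimulation charge (fast pool)
  double g_net = 0.0;          // stimulation-driven slow network suppression
  const double q_decay = std::exp(-tick_ms / stim_adapt_rise);
  double eff_amp = 0.0;        // effective amplitude of the ongoing pulse
  const double r_stim_rec = tick_ms / stim_dep_tau;

  for (int t = 0; t < n_ticks; ++t) {
    // -- afferent stimulation current for this tick --------------------
    bool stim_now = false;
    if (ext_stim[t]) stim_now = true;
    if (stim_pending) { stim_now = true; stim_pending = false; }
    if (stim_now) {
      stim_ticks.push_back(t);
      stim_active_until = t + stim_dur_ticks - 1;
      // short-term depression of the stimulation pathway: each pulse
      // releases a fraction of the remaining resource, so sustained trains
      // deliver charge in proportion to their active duration
      eff_amp = stim_amp * r_stim;
      q_stim += stim_adapt * r_stim;
      r_stim -= stim_dep_u * r_stim;
    }
    r_stim += (1.0 - r_stim) * r_stim_rec;
    const bool stim_on = (t <= stim_active_until);

    // -- network substeps ----------------------------------------------
    int eff_spikes = 0;
    for (int s = 0; s < substeps; ++s) {
      for (int i = 0; i < n; ++i) syn[i] *= syn_decay;
      for (int i = 0; i < n; ++i) {
        double I = noise_sd[i] * norm_rand() + syn[i] - g[i] - g_net;
        if (stim_on) I += eff_amp * stim_coupling[i];
        double vo = v[i];
        double vn = vo + dt * (0.04 * vo * vo + 5.0 * vo + 140.0 + I - u[i]);
        u[i] += dt * na[i] * (nb[i] * vo - u[i]);
        if (vn >= 30.0) {
          spike_neuron.push_back(i + 1);
          spike_ms.push_back(t * tick_ms + (s + 1) * dt);
          if (is_efferent[i]) ++eff_spikes;
          v[i] = nc[i];
          u[i] += nd[i];
          g[i] += slow_inc;
          // propagate with depression on excitatory synapses
          double res = is_exc[i] ? x[i] : 1.0;
          for (int k = pre_ptr[i]; k < pre_ptr[i + 1]; ++k)
            syn[post_idx[k]] += w[k] * res;
          if (is_exc[i]) x[i] -= U_dep * x[i];
        } else {
          v[i] = std::min(vn, 30.0 - 1e-9);
        }
      }
    }
    eff_counts[t] = eff_spikes;

    // resource recovery and slow-adaptation decay (once per tick)
    for (int i = 0; i < n; ++i) {
      x[i] += (1.0 - x[i]) * x_rec;
      g[i] *= g_decay;
    }
    // two-stage cascade: charge pool feeds the slow suppression current,
    // so suppression peaks after the tap and gates the next burst
    g_net += q_stim * (1.0 - q_decay);
    q_stim *= q_decay;
    g_net *= g_decay;

    // -- efferent decoding / command -----------------------------------
    double theta_d = theta1;
    if (efferent_mode == 0) {
      bin_count += eff_spikes;
      if ((t + 1) % bin_ticks == 0) {
        if (bin_count >= s_thres && (t + 1) >= next_allowed) {
          ttl_onsets.push_back(t + 1);
          ttl_until = t + ttl_ticks;      // pulse covers ticks t+1 .. t+ttl
          next_allowed = ttl_until + 1;
        }
        bin_count = 0;
      }
      if (t <= ttl_until) theta_d = theta2;
    } else if (efferent_mode == 1) {
      int phase = t % es_period_ticks;
      theta_d = (phase < es_period_ticks / 2) ? theta1 : theta2;
    }

    // -- plant ----------------------------------------------------------
    // asymmetric servo: tendon-driven flexion is faster than release
    theta = theta_d + (theta - theta_d) *
      (theta_d >= theta ? alpha_plant : alpha_release);
    theta_series[t] = theta;
    // viscoelastic fingertip: small angle flutter inside the deadband does
    // not modulate the contact force
    if (theta - theta_eff > deadband) theta_eff = theta - deadband;
    else if (theta_eff - theta > deadband) theta_eff = theta + deadband;
    double pen = theta_eff - theta_c;
    double f_raw = 0.0;
    if (pen > 0) {
      f_raw = stiffness * pen;
      if (force_noise_sd > 0) f_raw += force_noise_sd * norm_rand();
      if (f_raw < 0) f_raw = 0;
    }
    fdc_series[t] = f_raw;
    // trailing moving average then 3-sample centered difference (one-tick lag)
    raw_sum += f_raw - raw_ring[raw_pos];
    raw_ring[raw_pos] = f_raw;
    raw_pos = (raw_pos + 1) % raw_ring.size();
    double f_smooth = raw_sum / raw_ring.size();
    double f_ac = (f_smooth - fs_prev2) / (2.0 * tick_s);
    fac_series[t] = f_ac;
    fs_prev2 = fs_prev1;
    fs_prev1 = f_smooth;

    // -- afferent encoder ----------------------------------------------
    if (run_encoder) {
      double I_enc = (enc_mode == 0)
        ? enc_beta + k_sa * f_raw + k_ra * std::fabs(f_ac)
        : enc_alpha + k_ra * std::fabs(f_ac);
      bool spiked = false;
      for (int s = 0; s < substeps; ++s) {
        double vo = ev;
        ev += dt * (e_X * vo * vo + e_Y * vo + e_Z + I_enc - eu);
        eu += dt * e_a * (e_b * vo - eu);
        if (ev >= 30.0) { ev = e_c; eu += e_d; spiked = true; }
      }
      if (spiked) {
        enc_ticks.push_back(t);
        if (deliver_stim) stim_pending = true;  // one-tick loop latency
      }
    }
  }

  return List::create(
    _["spike_neuron"] = wrap(spike_neuron),
    _["spike_time_ms"] = wrap(spike_ms),
    _["encoder_ticks"] = wrap(enc_ticks),
    _["stim_ticks"] = wrap(stim_ticks),
    _["ttl_onset_ticks"] = wrap(ttl_onsets),
    _["theta"] = theta_series,
    _["f_dc"] = fdc_series,
    _["f_ac"] = fac_series,
    _["efferent_counts"] = eff_counts);
}
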