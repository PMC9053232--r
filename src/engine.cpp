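#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <deque>
using namespace Rcpp;

// positive modulo without std::fmod (keeps the symbol set portable)
static inline double wrap_deg(double theta_rad) {
  double deg = theta_rad * (180.0 / M_PI);
  double w = deg - 360.0 * std::floor(deg / 360.0);
  return (w >= 360.0) ? 0.0 : w;
}

// ---------------------------------------------------------------------------
// Causal preprocessing: first-order high-pass (RC) + biquad 50 Hz notch.
// Output at sample n depends only on samples <= n (real-time contract).
// ---------------------------------------------------------------------------

struct HighPass1 {
  double a, xprev, yprev;
  HighPass1(double fc, double fs) {
    double rc = 1.0 / (2.0 * M_PI * fc);
    a = rc / (rc + 1.0 / fs);
    xprev = yprev = 0.0;
  }
  double step(double x) {
    double y = a * (yprev + x - xprev);
    xprev = x; yprev = y;
    return y;
  }
};

struct BiquadNotch {
  double b0, b1, b2, a1, a2, x1, x2, y1, y2;
  BiquadNotch(double f0, double q, double fs) {
    double w0 = 2.0 * M_PI * f0 / fs;
    double alpha = std::sin(w0) / (2.0 * q);
    double a0 = 1.0 + alpha;
    b0 = 1.0 / a0; b1 = -2.0 * std::cos(w0) / a0; b2 = 1.0 / a0;
    a1 = -2.0 * std::cos(w0) / a0; a2 = (1.0 - alpha) / a0;
    x1 = x2 = y1 = y2 = 0.0;
  }
  double step(double x) {
    double y = b0 * x + b1 * x1 + b2 * x2 - a1 * y1 - a2 * y2;
    x2 = x1; x1 = x; y2 = y1; y1 = y;
    return y;
  }
};

// [[Rcpp::export]]
List cpp_preprocess(NumericVector x, double fs, double notch_freq,
                    double notch_q, double hp_cutoff) {
  int n = x.size();
  NumericVector out(n);
  LogicalVector qc(n);
  HighPass1 hp(hp_cutoff, fs);
  BiquadNotch notch(notch_freq, notch_q, fs);
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    if (!std::isfinite(v)) { qc[i] = true; v = 0.0; }
    out[i] = notch.step(hp.step(v));
  }
  return List::create(_["samples"] = out, _["qc"] = qc);
}

// ---------------------------------------------------------------------------
// Band power by direct DFT over a rectangular window: contribution of the
// band's bins to the signal variance (uV^2). Bin centers at k / window_sec.
// ---------------------------------------------------------------------------

struct BandDFT {
  int W;
  std::vector<int> bins;
  std::vector<double> ct, st;  // flattened [bin][i]
  BandDFT() : W(0) {}
  BandDFT(double lo, double hi, double window_sec, double fs) {
    W = (int)std::lround(window_sec * fs);
    int klo = (int)std::ceil(lo * window_sec - 1e-9);
    int khi = (int)std::floor(hi * window_sec + 1e-9);
    for (int k = klo; k <= khi; ++k) if (k > 0 && 2 * k < W) bins.push_back(k);
    ct.resize(bins.size() * W);
    st.resize(bins.size() * W);
    for (size_t b = 0; b < bins.size(); ++b)
      for (int i = 0; i < W; ++i) {
        double ang = 2.0 * M_PI * bins[b] * i / W;
        ct[b * W + i] = std::cos(ang);
        st[b * W + i] = std::sin(ang);
      }
  }
  // power over the last W samples ending at ring position; buf is contiguous
  double power(const double* buf) const {
    double tot = 0.0;
    for (size_t b = 0; b < bins.size(); ++b) {
      double re = 0.0, im = 0.0;
      const double* c = &ct[b * W];
      const double* s = &st[b * W];
      for (int i = 0; i < W; ++i) { re += buf[i] * c[i]; im += buf[i] * s[i]; }
      tot += 2.0 * (re * re + im * im) / ((double)W * W);
    }
    return tot;
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_band_power_track(NumericVector x, double fs,
                                   double window_sec, NumericMatrix bands) {
  // bands: one row per band, columns lo, hi. One row of output per second,
  // computed over the trailing window; NA until the buffer is full.
  int n = x.size();
  int fsi = (int)std::lround(fs);
  int W = (int)std::lround(window_sec * fs);
  int nsec = n / fsi;
  std::vector<BandDFT> dfts;
  for (int b = 0; b < bands.nrow(); ++b)
    dfts.emplace_back(bands(b, 0), bands(b, 1), window_sec, fs);
  NumericMatrix out(nsec, bands.nrow());
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> buf(W);
  for (int s = 0; s < nsec; ++s) {
    int end = (s + 1) * fsi;  // samples [end - W, end)
    if (end < W) continue;
    for (int i = 0; i < W; ++i) buf[i] = x[end - W + i];
    for (size_t b = 0; b < dfts.size(); ++b)
      out(s, b) = dfts[b].power(buf.data());
  }
  return out;
}

// ---------------------------------------------------------------------------
// First-order PLL. Phase detector: sign(input) * cos(theta); the numerically
// controlled oscillator advances at center_freq plus gain * error (Hz).
// Locked state: theta tracks the phase of sin-convention input (0 deg at the
// positive-going zero crossing, 90 deg at the positive peak).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_pll_track(NumericVector x, double fs, double center_freq,
                            double gain, double init_phase_rad) {
  int n = x.size();
  NumericVector out(n);
  double theta = init_phase_rad;
  for (int i = 0; i < n; ++i) {
    double sg = (x[i] > 0) - (x[i] < 0);
    double e = sg * std::cos(theta);
    theta += 2.0 * M_PI * (center_freq + gain * e) / fs;
    out[i] = wrap_deg(theta);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Full closed-loop night: generator components in, stimulation log out.
// ---------------------------------------------------------------------------

struct Effect { long end; double factor; };

// [[Rcpp::export]]
List cpp_run_night(NumericVector phase, NumericVector sw_amp,
                   NumericVector bg, double fs, List cfg,
                   double g, double r, double dur_cycles) {
  const int n = phase.size();
  const int fsi = (int)std::lround(fs);

  // config
  const double notch_freq = cfg["notch_freq"], notch_q = cfg["notch_q"],
    hp_cutoff = cfg["hp_cutoff"];
  const double ld_min = cfg["low_delta_min"], hd_min = cfg["high_delta_min"],
    nrem_beta_max = cfg["nrem_beta_max"], sws_delta_min = cfg["sws_delta_min"],
    beta_veto_max = cfg["beta_veto_max"];
  const int stable_initial = (int)cfg["stable_nrem_initial"];
  const int stable_followup = (int)cfg["stable_nrem_followup"];
  const double target_deg = cfg["target_phase"], refractory = cfg["refractory"],
    amp_ceiling = cfg["amplitude_ceiling"];
  const double vol_default = cfg["volume_default"], vol_min = cfg["volume_min"],
    vol_max = cfg["volume_max"], vol_step = cfg["volume_step"];
  const int tones_before_increase = (int)cfg["tones_before_increase"];
  const int arousals_before_decrease = (int)cfg["arousals_before_decrease"];
  const bool verum = as<bool>(cfg["verum"]);
  const bool windowed = as<bool>(cfg["windowed"]);
  const int window_samp = (int)std::lround((double)cfg["window_len"] * fs);
  const double pll_center = cfg["pll_center_freq"], pll_gain = cfg["pll_gain"];
  const double bp_window = cfg["bp_window"];
  const double arousal_eval = cfg["arousal_eval_window"];

  BandDFT dft_ld(as<NumericVector>(cfg["low_delta_band"])[0],
                 as<NumericVector>(cfg["low_delta_band"])[1], bp_window, fs);
  BandDFT dft_hd(as<NumericVector>(cfg["high_delta_band"])[0],
                 as<NumericVector>(cfg["high_delta_band"])[1], bp_window, fs);
  BandDFT dft_hb(as<NumericVector>(cfg["high_beta_band"])[0],
                 as<NumericVector>(cfg["high_beta_band"])[1], bp_window, fs);
  BandDFT dft_b1(as<NumericVector>(cfg["high_beta_band"])[0],
                 as<NumericVector>(cfg["high_beta_band"])[1], 1.0, fs);
  const int W4 = dft_ld.W, W1 = dft_b1.W;

  HighPass1 hp(hp_cutoff, fs);
  BiquadNotch notch(notch_freq, notch_q, fs);

  // state
  std::vector<double> fbuf((size_t)n);  // filtered stream (for DFT windows)
  NumericVector eeg_out(n);
  double theta = 0.0;
  long last_cycle = -1; bool fired_this_cycle = false;
  bool nrem = false, sws = false, beta_veto = false, stim_en = false,
    first_done = false;
  int stable = 0;
  long window_anchor = -1;
  double baseline_start = NA_REAL, baseline_end = NA_REAL;
  double volume = vol_default;
  int consec_quiet = 0, consec_arousal = 0;
  double last_event_t = -1e9;
  std::deque<Effect> effects;
  int train_k = 0; long train_end = -1;
  struct PendingTone { double t; bool depth_ok; };
  std::deque<PendingTone> pending;

  const int nsec = n / fsi;
  std::vector<double> beta1_hist((size_t)std::max(nsec, 1), 0.0);
  IntegerVector tr_nrem(nsec), tr_sws(nsec), tr_beta(nsec), tr_en(nsec),
    tr_win(nsec);  // 0 none, 1 ON, 2 OFF
  NumericVector tr_vol(nsec);
  LogicalVector qc_sec(nsec);

  std::vector<double> ev_t, ev_vol, ev_phase;
  std::vector<int> ev_kind, ev_win, ev_widx;  // kind 1 tone, 2 trigger
  long veto_refractory = 0, veto_negative = 0, veto_amplitude = 0,
    veto_beta = 0, veto_gate = 0;

  std::vector<double> dbuf((size_t)W4);
  const double dphi = dur_cycles * 2.0 * M_PI;

  for (int i = 0; i < n; ++i) {
    // generator sample under active evoked effects
    while (!effects.empty() && effects.front().end < i) effects.pop_front();
    double m = 1.0;
    for (const Effect& ef : effects) m *= ef.factor;
    double x = m * sw_amp[i] * std::sin(phase[i]) + bg[i];
    eeg_out[i] = x;
    int sec_now = i / fsi;
    if (!std::isfinite(x)) { x = 0.0; if (sec_now < nsec) qc_sec[sec_now] = true; }
    double fx = notch.step(hp.step(x));
    fbuf[(size_t)i] = fx;

    // PLL
    double sg = (fx > 0) - (fx < 0);
    theta += 2.0 * M_PI * (pll_center + pll_gain * sg * std::cos(theta)) / fs;
    long cyc = (long)std::floor(theta / (2.0 * M_PI));
    if (cyc != last_cycle) { last_cycle = cyc; fired_this_cycle = false; }
    double est_deg = wrap_deg(theta);

    // target-phase crossing, latched once per PLL cycle
    if (!fired_this_cycle && est_deg >= target_deg &&
        est_deg < target_deg + 180.0) {
      fired_this_cycle = true;
      double t = (double)i / fs;
      int widx = -1; bool on_window = false, off_window = false;
      if (windowed && stim_en && window_anchor >= 0 && i >= window_anchor) {
        widx = (int)((i - window_anchor) / window_samp);
        on_window = (widx % 2 == 0);
        off_window = !on_window;
      }
      bool gates_ok = stim_en && sws && !beta_veto;
      if (!stim_en || !sws) ++veto_gate;
      else if (beta_veto) ++veto_beta;
      else if (fx <= 0) ++veto_negative;
      else if (std::fabs(fx) > amp_ceiling) ++veto_amplitude;
      else if (t - last_event_t < refractory) ++veto_refractory;
      else if (gates_ok) {
        bool eligible = !windowed || on_window || off_window;
        if (eligible) {
          bool stim_slot = !windowed || on_window;  // OFF = marker only
          int kind = (verum && stim_slot) ? 1 : 2;
          ev_t.push_back(t); ev_kind.push_back(kind);
          ev_vol.push_back(volume); ev_phase.push_back(est_deg);
          ev_win.push_back(windowed ? (on_window ? 1 : 2) : 0);
          ev_widx.push_back(widx);
          last_event_t = t;
          if (stim_slot) {
            pending.push_back({t, sws});
            if (verum && g > 0) {
              train_k = (i <= train_end) ? train_k + 1 : 1;
              long e = i;
              double tgt = phase[i] + dphi;
              while (e < n - 1 && phase[e] < tgt) ++e;
              double vw = 0.8 + 0.4 * (volume - 46.0) / 14.0;
              double fac = 1.0 + g * vw * std::pow(r, train_k - 1);
              effects.push_back({e, fac});
              if (e > train_end) train_end = e;
            }
          }
        }
      }
    }

    // once per second: band powers, gates, volume controller
    if ((i + 1) % fsi == 0) {
      int sec = (i + 1) / fsi - 1;  // the second just completed
      if (i + 1 >= W4) {
        const double* tail4 = &fbuf[(size_t)(i + 1 - W4)];
        for (int j = 0; j < W4; ++j) dbuf[(size_t)j] = tail4[j];
        double p_ld = dft_ld.power(dbuf.data());
        double p_hd = dft_hd.power(dbuf.data());
        double p_hb = dft_hb.power(dbuf.data());
        double p_b1 = dft_b1.power(&fbuf[(size_t)(i + 1 - W1)]);
        beta1_hist[(size_t)sec] = p_b1;

        nrem = (p_ld >= ld_min) && (p_hd >= hd_min) && (p_hb <= nrem_beta_max);
        if (nrem) ++stable; else { stable = 0; stim_en = false; }
        int need = first_done ? stable_followup : stable_initial;
        if (!stim_en && stable >= need) {
          stim_en = true;
          window_anchor = (long)(i + 1);
          if (!first_done) {
            first_done = true;
            baseline_end = (double)(i + 1) / fs;
            baseline_start = baseline_end - stable_initial;
          }
        }
        sws = (p_ld >= sws_delta_min);
        beta_veto = (p_b1 > beta_veto_max);

        if (p_ld < 0.5 * sws_delta_min) {  // minimum-delta condition fails
          volume = vol_default; consec_quiet = 0; consec_arousal = 0;
        }
        // evaluate tones whose post-stimulus window has elapsed
        double now = (double)(i + 1) / fs;
        while (!pending.empty() && pending.front().t + arousal_eval <= now) {
          PendingTone pt = pending.front(); pending.pop_front();
          bool arousal = false;
          int s0 = (int)std::floor(pt.t);
          for (int s2 = s0 + 1; s2 <= s0 + (int)arousal_eval && s2 < nsec; ++s2)
            if (beta1_hist[(size_t)s2] > beta_veto_max) { arousal = true; break; }
          if (arousal) {
            consec_quiet = 0;
            if (++consec_arousal >= arousals_before_decrease) {
              volume = std::max(vol_min, volume - vol_step);
              consec_arousal = 0;
            }
          } else {
            consec_arousal = 0;
            if (pt.depth_ok && ++consec_quiet >= tones_before_increase) {
              volume = std::min(vol_max, volume + vol_step);
              consec_quiet = 0;
            }
          }
        }
      }
      // row `sec` = classification of the second just completed; the
      // decision stack consumes it from the next second (1-s latency)
      tr_nrem[sec] = nrem; tr_sws[sec] = sws;
      tr_beta[sec] = beta_veto; tr_en[sec] = stim_en;
      int wl = 0;
      long samp0 = (long)sec * fsi;
      if (windowed && stim_en && window_anchor >= 0 && samp0 >= window_anchor)
        wl = (((samp0 - window_anchor) / window_samp) % 2 == 0) ? 1 : 2;
      tr_win[sec] = wl;
      tr_vol[sec] = volume;
    }
  }

  int ne = ev_t.size();
  CharacterVector kind_out(ne), win_out(ne);
  for (int k = 0; k < ne; ++k) {
    kind_out[k] = (ev_kind[k] == 1) ? "tone" : "trigger";
    win_out[k] = (ev_win[k] == 1) ? "ON" : (ev_win[k] == 2 ? "OFF" : "NA");
  }
  return List::create(
    _["t_s"] = wrap(ev_t), _["kind"] = kind_out,
    _["volume_db"] = wrap(ev_vol), _["phase_est_deg"] = wrap(ev_phase),
    _["window_label"] = win_out, _["window_index"] = wrap(ev_widx),
    _["track"] = DataFrame::create(
      _["second"] = seq_len(nsec) - 1,
      _["nrem"] = tr_nrem, _["sws"] = tr_sws, _["beta_veto"] = tr_beta,
      _["stim_enabled"] = tr_en, _["window"] = tr_win,
      _["volume_db"] = tr_vol),
    _["baseline_start"] = baseline_start, _["baseline_end"] = baseline_end,
    _["qc_sec"] = qc_sec, _["eeg"] = eeg_out,
    _["vetoes"] = NumericVector::create(
      _["gate"] = (double)veto_gate, _["beta"] = (double)veto_beta,
      _["negative_amplitude"] = (double)veto_negative,
      _["amplitude_ceiling"] = (double)veto_amplitude,
      _["refractory"] = (double)veto_refractory));
}
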