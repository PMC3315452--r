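#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven integration of the fully connected conductance-based
// integrate-and-fire network. Neurons are grouped contiguously by
// population; with uniform block weights the recurrent input of a neuron
// depends on presynaptic gating only through per-population sums, giving
// O(N + P^2) cost per step ("blocked" path). The naive O(N^2) per-synapse
// path is kept for equivalence testing on miniature networks.
//
// Units: time ms, voltage mV, conductance nS, capacitance pF, rates kHz.
// With these, dt * g / Cm is dimensionless and dt * g * V / Cm is in mV.
//
// Update order per step (spikes take effect on gating at the next step):
//   1. background OU rates + external Poisson arrivals
//   2. gating decay + jumps from the previous step's spikes; population sums
//   3. membrane Euler update, threshold test, reset/refractory

// [[Rcpp::export]]
List sim_network_cpp(IntegerVector pop_of,        // 0-based population per neuron
                     IntegerVector pop_size,
                     IntegerVector pop_is_exc,    // 1 = excitatory population
                     NumericMatrix W,             // [pre, post] block weights
                     NumericVector exc_par,       // cm_pF, gl, vl, vthr, vreset, tref
                     NumericVector inh_par,
                     NumericVector g_exc,         // g_ext, g_ampa, g_nmda, g_gaba (post = E)
                     NumericVector g_inh,         // same for post = I
                     NumericVector syn,           // ve, vi, tau_ampa, tau_x, tau_nmda, tau_gaba, alpha, mg_gamma, mg_beta
                     NumericVector bg,            // nu0, sigma_nu (kHz), tau_n (ms)
                     NumericMatrix stim,          // rows: pop (0-based), onset, offset, rate_khz
                     double duration, double dt,
                     bool include_self, bool naive,
                     int rate_sample_every) {
  const int N = pop_of.size();
  const int P = pop_size.size();
  if (dt <= 0 || dt > 0.1) stop("dt must be in (0, 0.1] ms for stability");
  const int nsteps = (int)std::lround(duration / dt);

  const double ve = syn[0], vi = syn[1];
  const double tau_a = syn[2], tau_x = syn[3], tau_n = syn[4], tau_g = syn[5];
  const double alpha = syn[6], mg_gamma = syn[7], mg_beta = syn[8];
  const double dec_a = std::exp(-dt / tau_a);
  const double dec_x = std::exp(-dt / tau_x);
  const double dec_g = std::exp(-dt / tau_g);

  const double nu0 = bg[0], sig = bg[1], tau_bg = bg[2];
  const double ou_drift = dt / tau_bg;
  const double ou_diff = sig * std::sqrt(2.0 * dt / tau_bg);

  std::vector<int> pop_off(P, 0);
  for (int p = 1; p < P; ++p) pop_off[p] = pop_off[p - 1] + pop_size[p - 1];

  // per-neuron class parameters
  std::vector<double> cm(N), gl(N), vl(N), vthr(N), vres(N);
  std::vector<int> ref_steps(N);
  std::vector<double> ge(N), ga(N), gn(N), gg(N);
  for (int i = 0; i < N; ++i) {
    bool exc = pop_is_exc[pop_of[i]] == 1;
    const NumericVector& par = exc ? exc_par : inh_par;
    const NumericVector& g = exc ? g_exc : g_inh;
    cm[i] = par[0]; gl[i] = par[1]; vl[i] = par[2]; vthr[i] = par[3];
    vres[i] = par[4];
    ref_steps[i] = (int)std::lround(par[5] / dt);
    ge[i] = g[0]; ga[i] = g[1]; gn[i] = g[2]; gg[i] = g[3];
  }

  // state
  std::vector<double> V(N), sa(N, 0.0), x(N, 0.0), sn(N, 0.0), sg(N, 0.0),
      sext(N, 0.0);
  std::vector<int> refr(N, 0), cnt(N, 0), extc(N, 0);
  for (int i = 0; i < N; ++i)
    V[i] = vl[i] + (vthr[i] - vl[i]) * 0.5 * unif_rand(); // mild dispersion

  std::vector<double> nu(P);
  for (int p = 0; p < P; ++p)
    nu[p] = nu0 + (sig > 0 ? sig * norm_rand() : 0.0);

  std::vector<double> SA(P), SN(P), SG(P), WA(P), WN(P), WG(P), extra(P);
  std::vector<int> spk_neuron;
  std::vector<double> spk_time;
  spk_neuron.reserve(4096);
  spk_time.reserve(4096);

  const int n_stim = stim.nrow();
  const bool record = rate_sample_every > 0;
  std::vector<double> rate_rec;
  std::vector<double> rate_times;

  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    // --- background rates and external arrivals ---
    for (int p = 0; p < P; ++p) {
      if (sig > 0 || std::abs(nu[p] - nu0) > 1e-15)
        nu[p] += (nu0 - nu[p]) * ou_drift + (sig > 0 ? ou_diff * norm_rand() : 0.0);
      extra[p] = 0.0;
    }
    for (int s = 0; s < n_stim; ++s)
      if (t >= stim(s, 1) && t < stim(s, 2)) extra[(int)stim(s, 0)] += stim(s, 3);
    for (int p = 0; p < P; ++p) {
      double rate = (nu[p] > 0 ? nu[p] : 0.0) + extra[p]; // kHz per neuron
      if (rate <= 0) continue;
      double lam = rate * dt * pop_size[p];
      int k = (int)R::rpois(lam);
      for (int j = 0; j < k; ++j) {
        int idx = pop_off[p] + (int)(unif_rand() * pop_size[p]);
        if (idx >= pop_off[p] + pop_size[p]) idx = pop_off[p] + pop_size[p] - 1;
        extc[idx] += 1;
      }
    }
    if (record && step % rate_sample_every == 0) {
      rate_times.push_back(t);
      for (int p = 0; p < P; ++p)
        rate_rec.push_back((nu[p] > 0 ? nu[p] : 0.0) + extra[p]);
    }

    // --- gating update (consumes previous-step spikes) + population sums ---
    for (int p = 0; p < P; ++p) { SA[p] = 0.0; SN[p] = 0.0; SG[p] = 0.0; }
    for (int i = 0; i < N; ++i) {
      const int p = pop_of[i];
      if (pop_is_exc[p]) {
        double s = sn[i];
        s += dt * (-s / tau_n + alpha * x[i] * (1.0 - s));
        if (s > 1.0) s = 1.0; else if (s < 0.0) s = 0.0;
        sn[i] = s;
        x[i] = x[i] * dec_x + cnt[i];
        sa[i] = sa[i] * dec_a + cnt[i];
        SA[p] += sa[i];
        SN[p] += s;
      } else {
        sg[i] = sg[i] * dec_g + cnt[i];
        SG[p] += sg[i];
      }
      cnt[i] = 0;
      sext[i] = sext[i] * dec_a + extc[i];
      extc[i] = 0;
    }
    for (int q = 0; q < P; ++q) {
      double wa = 0.0, wn = 0.0, wg = 0.0;
      for (int p = 0; p < P; ++p) {
        if (pop_is_exc[p]) { wa += W(p, q) * SA[p]; wn += W(p, q) * SN[p]; }
        else wg += W(p, q) * SG[p];
      }
      WA[q] = wa; WN[q] = wn; WG[q] = wg;
    }

    // --- membrane update ---
    const double tnext = t + dt;
    for (int i = 0; i < N; ++i) {
      if (refr[i] > 0) { --refr[i]; V[i] = vres[i]; continue; }
      const int q = pop_of[i];
      double in_a, in_n, in_g;
      if (!naive) {
        in_a = WA[q]; in_n = WN[q]; in_g = WG[q];
        if (!include_self) {
          if (pop_is_exc[q]) { in_a -= W(q, q) * sa[i]; in_n -= W(q, q) * sn[i]; }
          else in_g -= W(q, q) * sg[i];
        }
      } else {
        in_a = 0.0; in_n = 0.0; in_g = 0.0;
        for (int j = 0; j < N; ++j) {
          if (!include_self && j == i) continue;
          const int p = pop_of[j];
          if (pop_is_exc[p]) { in_a += W(p, q) * sa[j]; in_n += W(p, q) * sn[j]; }
          else in_g += W(p, q) * sg[j];
        }
      }
      double v = V[i];
      const double mg = 1.0 / (1.0 + mg_gamma * std::exp(-mg_beta * v));
      const double isyn = ge[i] * sext[i] * (v - ve) + ga[i] * in_a * (v - ve) +
                          gn[i] * mg * in_n * (v - ve) + gg[i] * in_g * (v - vi);
      v += dt * (-gl[i] * (v - vl[i]) - isyn) / cm[i];
      if (v > 100.0 || v < -200.0 || v != v)
        stop("membrane potential diverged (neuron %d, t = %.2f ms); reduce dt",
             i + 1, tnext);
      if (v >= vthr[i]) {
        spk_neuron.push_back(i + 1);
        spk_time.push_back(tnext < duration ? tnext : duration);
        cnt[i] = 1;
        v = vres[i];
        refr[i] = ref_steps[i];
      }
      V[i] = v;
    }
  }

  List out = List::create(
      _["neuron"] = IntegerVector(spk_neuron.begin(), spk_neuron.end()),
      _["time_ms"] = NumericVector(spk_time.begin(), spk_time.end()));
  if (record) {
    const int nr = rate_times.size();
    NumericMatrix rm(nr, P);
    for (int r = 0; r < nr; ++r)
      for (int p = 0; p < P; ++p) rm(r, p) = rate_rec[(size_t)r * P + p];
    out["rate_times_ms"] = NumericVector(rate_times.begin(), rate_times.end());
    out["rates_khz"] = rm;
  }
  return out;
}

// Monte-Carlo firing rate of a leaky IF neuron driven by Gaussian white
// noise with stationary mean mu and std sigma (Euler-Maruyama). Serves as
// the independent first-passage oracle for the analytic transfer function.
// [[Rcpp::export]]
double sim_lif_rate_cpp(double mu, double sigma, double tau_m, double tau_ref,
                        double v_thr, double v_reset, double duration,
                        double dt) {
  if (dt <= 0 || tau_m <= 0) stop("invalid dt or tau_m");
  const int nsteps = (int)std::lround(duration / dt);
  const double drift = dt / tau_m;
  const double diff = sigma * std::sqrt(2.0 * dt / tau_m);
  double v = v_reset;
  int ref = 0;
  const int ref_steps = (int)std::lround(tau_ref / dt);
  long spikes = 0;
  for (int s = 0; s < nsteps; ++s) {
    if (ref > 0) { --ref; continue; }
    v += (mu - v) * drift + diff * norm_rand();
    if (v >= v_thr) { ++spikes; v = v_reset; ref = ref_steps; }
  }
  return 1000.0 * spikes / duration; // Hz
}

// Stationary mean of the NMDA gating variable for a Poisson presynaptic
// train at the given rates: integrates x' = -x/tau_x + spikes,
// s' = -s/tau_d + alpha*x*(1-s) and time-averages s after a burn-in.
// [[Rcpp::export]]
NumericVector nmda_gating_mc_cpp(NumericVector rate_khz, double tau_x,
                                 double tau_d, double alpha, double duration,
                                 double dt) {
  const int K = rate_khz.size();
  const int nsteps = (int)std::lround(duration / dt);
  const int burn = (int)std::lround(1000.0 / dt); // 1 s burn-in
  const double dec_x = std::exp(-dt / tau_x);
  NumericVector out(K);
  for (int k = 0; k < K; ++k) {
    double lam = rate_khz[k] * dt;
    double x = 0.0, s = 0.0, acc = 0.0;
    long n = 0;
    for (int st = 0; st < nsteps; ++st) {
      s += dt * (-s / tau_d + alpha * x * (1.0 - s));
      if (s > 1.0) s = 1.0;
      x = x * dec_x + (lam > 0 ? R::rpois(lam) : 0.0);
      if (st >= burn) { acc += s; ++n; }
    }
    out[k] = n > 0 ? acc / n : 0.0;
  }
  return out;
}
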