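// Core simulation engine: random connectivity sampling and forward-Euler
// integration of the LIF network with short-term plasticity and delayed
// delta synapses.  All heavy loops live here; R wrappers validate inputs.
#include <Rcpp.h>
#include "rng.h"
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weight classes (must match R side): 0 = EE, 1 = EI (E->I), 2 = IE (I->E),
// 3 = II.  Only EE and EI are dopamine-scaled; only EE carries STP.
enum WClass { W_EE = 0, W_EI = 1, W_IE = 2, W_II = 3 };

// Sample the directed Erdos-Renyi connectivity with population-dependent
// weight classes.  pop[i]: 0..p-1 selective Es populations, p = Ens,
// p+1 = I.  Returns CSR-by-presynaptic-neuron arrays.
// Delays are uniform on (0, 1] ms, quantized UP to the dt grid (>= 1 step).
// [[Rcpp::export]]
List cpp_sample_connectivity(IntegerVector pop, int n_items,
                             double c, double gamma,
                             double J_b, double J_p,
                             double J_EI, double J_IE, double J_II,
                             double dt, double max_delay_ms,
                             double seed) {
  const int N = pop.size();
  const int ENS = n_items;        // Ens label
  const int INH = n_items + 1;    // I label
  pfcwm::Xoshiro256 rng(static_cast<uint64_t>(seed));

  const int max_steps = std::max(1, (int)std::lround(max_delay_ms / dt));

  std::vector<int> ptr(N + 1, 0);
  std::vector<int> post;
  std::vector<double> w;
  std::vector<unsigned char> wclass, delay;
  if (c > 0) {
    size_t guess = (size_t)((double)N * N * c * 1.02) + 64;
    post.reserve(guess); w.reserve(guess);
    wclass.reserve(guess); delay.reserve(guess);
  }

  const double logq = (c > 0.0 && c < 1.0) ? std::log1p(-c) : 0.0;

  for (int j = 0; j < N; ++j) {
    ptr[j] = (int)post.size();
    if (c <= 0.0) continue;
    int i = -1;
    while (true) {
      if (c >= 1.0) {
        ++i;
      } else {
        double u = rng.unif();
        if (u <= 0.0) u = std::numeric_limits<double>::min();
        double skip = std::floor(std::log(u) / logq);
        if (skip > (double)(2 * N)) break;
        i += 1 + (int)skip;
      }
      if (i >= N) break;
      if (i == j) continue;
      const int pj = pop[j], pi = pop[i];
      unsigned char cls; double ww;
      if (pj == INH) {
        if (pi == INH) { cls = W_II; ww = J_II; }
        else           { cls = W_IE; ww = J_IE; }
      } else if (pi == INH) {
        cls = W_EI; ww = J_EI;
      } else {
        cls = W_EE;
        if (pj < ENS && pi < ENS) {
          ww = (pj == pi) ? J_p : J_b;
        } else {
          // any endpoint in Ens: potentiated with probability gamma
          ww = (rng.unif() < gamma) ? J_p : J_b;
        }
      }
      // delay uniform on (0, max_delay]; ceil to grid, minimum one step
      double d_ms = rng.unif() * max_delay_ms;
      int d = (int)std::ceil(d_ms / dt);
      if (d < 1) d = 1;
      if (d > max_steps) d = max_steps;
      post.push_back(i);
      w.push_back(ww);
      wclass.push_back(cls);
      delay.push_back((unsigned char)d);
    }
  }
  ptr[N] = (int)post.size();

  return List::create(
    _["ptr"] = IntegerVector(ptr.begin(), ptr.end()),
    _["post"] = IntegerVector(post.begin(), post.end()),
    _["w"] = NumericVector(w.begin(), w.end()),
    _["wclass"] = IntegerVector(wclass.begin(), wclass.end()),
    _["delay_steps"] = IntegerVector(delay.begin(), delay.end()),
    _["max_delay_steps"] = max_steps);
}

// Forward-Euler integration of the coupled LIF + STP dynamics.
//
// Per step and neuron:  V += (dt/tau)(mu_eff - V) + sigma*sqrt(dt/tau)*xi
//                          + delayed synaptic deposits
// Spike: V >= theta -> reset V_r, refractory tau_arp (deposits arriving
// during refractoriness are discarded).  On a presynaptic E spike the
// utilization jumps first (u <- u + U(1-u)), the transmitted E->E efficacy
// is J * u_post_jump * x_pre_jump, then x <- x - u*x; both relax toward
// (U, X) continuously.
// [[Rcpp::export]]
List cpp_run_network(List net, IntegerVector pop, int n_E, int n_pop_E,
                     NumericVector theta, NumericVector V_r,
                     NumericVector tau_m, NumericVector mu_ext,
                     NumericVector sigma_ext,
                     double A_EE, double A_EI,
                     NumericMatrix stimuli, // cols: pop, onset_ms, offset_ms, factor
                     double duration, double dt,
                     double tau_arp, double U, double X,
                     double tau_u, double tau_x,
                     IntegerVector record_neurons, double sample_ms,
                     double seed, double v_guard) {
  const int N = pop.size();
  IntegerVector ptr = net["ptr"], post = net["post"];
  IntegerVector wclass = net["wclass"], delay = net["delay_steps"];
  NumericVector w = net["w"];
  const int max_delay = as<int>(net["max_delay_steps"]);
  const int RING = max_delay + 1;
  const int n_steps = (int)std::lround(duration / dt);
  const int arp_steps = (int)std::lround(tau_arp / dt);
  const int steps_per_bin = std::max(1, (int)std::lround(sample_ms / dt));
  const int n_bins = (n_steps + steps_per_bin - 1) / steps_per_bin;

  pfcwm::Xoshiro256 rng(static_cast<uint64_t>(seed));
  const pfcwm::Ziggurat &zig = pfcwm::ziggurat();

  // state
  std::vector<double> V(N), u(n_E, U), x(n_E, X), fac(N, 1.0);
  std::vector<int> refrac(N, 0);
  for (int i = 0; i < N; ++i) V[i] = V_r[i] + rng.unif() * (theta[i] - V_r[i]);

  // precomputed per-neuron coefficients
  // white-noise current convention: tau V' = -V + mu + sigma sqrt(tau) eta
  // => per step V += (dt/tau)(mu - V) + sigma sqrt(dt/tau) xi, stationary
  // free-membrane SD = sigma/sqrt(2), independent of dt
  std::vector<double> a(N), noise_c(N);
  for (int i = 0; i < N; ++i) {
    a[i] = dt / tau_m[i];
    noise_c[i] = sigma_ext[i] * std::sqrt(dt / tau_m[i]);
  }

  // delayed-deposit ring buffers, separated E / I for current decomposition
  std::vector<double> bufE((size_t)RING * N, 0.0), bufI((size_t)RING * N, 0.0);

  // static dopamine-scaled weights
  std::vector<double> ws(w.size());
  for (int k = 0; k < (int)w.size(); ++k) {
    switch (wclass[k]) {
    case W_EE: ws[k] =  A_EE * w[k]; break;
    case W_EI: ws[k] =  A_EI * w[k]; break;
    default:   ws[k] = -w[k];        break; // inhibitory deposits are negative
    }
  }

  // stimulus event schedule
  const int n_stim = stimuli.nrow();
  std::vector<int> on_step(n_stim), off_step(n_stim);
  for (int s = 0; s < n_stim; ++s) {
    on_step[s] = (int)std::lround(stimuli(s, 1) / dt);
    off_step[s] = (int)std::lround(stimuli(s, 2) / dt);
  }

  // current recording
  const int n_rec = record_neurons.size();
  std::vector<int> recidx(N, -1);
  for (int r = 0; r < n_rec; ++r) recidx[record_neurons[r]] = r;
  NumericMatrix cur_e(n_bins, n_rec), cur_i(n_bins, n_rec),
                cur_ext(n_bins, n_rec), cur_leak(n_bins, n_rec);
  NumericMatrix u_rec(n_bins, n_rec), x_rec(n_bins, n_rec);

  // population-mean STP traces (E populations incl. Ens)
  NumericMatrix u_mean(n_bins, n_pop_E), x_mean(n_bins, n_pop_E);
  std::vector<double> pop_n(n_pop_E, 0.0);
  for (int i = 0; i < n_E; ++i) pop_n[pop[i]] += 1.0;
  std::vector<int> bin_steps(n_bins, 0);

  std::vector<double> spk_t; std::vector<int> spk_id;
  spk_t.reserve(1 << 16); spk_id.reserve(1 << 16);

  const double du_c = dt / tau_u, dx_c = dt / tau_x;
  bool blow_up = false;

  for (int step = 0; step < n_steps && !blow_up; ++step) {
    const int slot = step % RING;
    const int bin = step / steps_per_bin;
    bin_steps[bin]++;

    // stimulus on/off events
    for (int s = 0; s < n_stim; ++s) {
      if (step == on_step[s]) {
        int tp = (int)stimuli(s, 0);
        for (int i = 0; i < N; ++i) if (pop[i] == tp) fac[i] = stimuli(s, 3);
      }
      if (step == off_step[s]) {
        int tp = (int)stimuli(s, 0);
        for (int i = 0; i < N; ++i) if (pop[i] == tp) fac[i] = 1.0;
      }
    }

    // STP relaxation + population means
    for (int i = 0; i < n_E; ++i) {
      u[i] += du_c * (U - u[i]);
      x[i] += dx_c * (X - x[i]);
      u_mean(bin, pop[i]) += u[i];
      x_mean(bin, pop[i]) += x[i];
      if (recidx[i] >= 0) {
        u_rec(bin, recidx[i]) += u[i];
        x_rec(bin, recidx[i]) += x[i];
      }
    }

    const double t_spike = (step + 1) * dt;
    for (int i = 0; i < N; ++i) {
      const size_t bi = (size_t)slot * N + i;
      const double accE = bufE[bi], accI = bufI[bi];
      bufE[bi] = 0.0; bufI[bi] = 0.0;
      if (refrac[i] > 0) {          // deposits during refractoriness discarded
        --refrac[i];
        V[i] = V_r[i];
        if (recidx[i] >= 0) {       // but still *recorded* as received input
          cur_e(bin, recidx[i]) += accE;
          cur_i(bin, recidx[i]) += accI;
        }
        continue;
      }
      const double leak = -a[i] * V[i];
      const double ext = a[i] * mu_ext[i] * fac[i] + noise_c[i] * zig.draw(rng);
      V[i] += leak + ext + accE + accI;
      if (recidx[i] >= 0) {
        const int r = recidx[i];
        cur_e(bin, r) += accE;  cur_i(bin, r) += accI;
        cur_ext(bin, r) += ext; cur_leak(bin, r) += leak;
      }
      if (V[i] >= theta[i]) {
        spk_t.push_back(t_spike); spk_id.push_back(i);
        V[i] = V_r[i];
        refrac[i] = arp_steps;
        double stp_fac = 1.0;
        if (i < n_E) {
          u[i] += U * (1.0 - u[i]);       // facilitation jump (post-jump u)
          stp_fac = u[i] * x[i];          // transmitted with pre-jump x
          x[i] -= u[i] * x[i];            // resource consumption
        }
        for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
          const size_t tslot = (size_t)((step + delay[k]) % RING) * N + post[k];
          if (wclass[k] == W_EE)      bufE[tslot] += ws[k] * stp_fac;
          else if (wclass[k] == W_EI) bufE[tslot] += ws[k];
          else                        bufI[tslot] += ws[k];
        }
      } else if (std::fabs(V[i]) > v_guard) {
        blow_up = true;
      }
    }
  }
  if (blow_up)
    stop("membrane potential exceeded guard bound (|V| > %g mV): numerical blow-up", v_guard);

  // normalize binned means
  for (int b = 0; b < n_bins; ++b) {
    for (int q = 0; q < n_pop_E; ++q) {
      double denom = bin_steps[b] * std::max(pop_n[q], 1.0);
      u_mean(b, q) /= denom; x_mean(b, q) /= denom;
    }
    for (int r = 0; r < n_rec; ++r) {
      u_rec(b, r) /= bin_steps[b]; x_rec(b, r) /= bin_steps[b];
    }
  }

  return List::create(
    _["spike_t"] = NumericVector(spk_t.begin(), spk_t.end()),
    _["spike_id"] = IntegerVector(spk_id.begin(), spk_id.end()),
    _["cur_rec_exc"] = cur_e, _["cur_rec_inh"] = cur_i,
    _["cur_external"] = cur_ext, _["cur_leak"] = cur_leak,
    _["u_mean"] = u_mean, _["x_mean"] = x_mean,
    _["u_rec"] = u_rec, _["x_rec"] = x_rec,
    _["n_bins"] = n_bins, _["sample_ms"] = steps_per_bin * dt,
    _["V_final"] = NumericVector(V.begin(), V.end()));
}
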