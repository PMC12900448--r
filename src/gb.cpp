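// Pairing protocol for the calcium-based bistable synapse, batched over
// trials. Calcium is a deterministic function of the spike times and is
// advanced analytically per step (shared by all trials); the weight follows
// an Euler-Maruyama step per trial with threshold-gated noise drawn from
// per-trial counter-based streams.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// from rng.cpp
void threefry4x64_12(const uint64_t key[4], const uint64_t ctr[4],
                     uint64_t out[4]);
double u64_to_unit(uint64_t v);

namespace {
double tf_u01(uint64_t seed, uint64_t a, uint64_t b, uint64_t c,
              uint64_t counter, int slot) {
  uint64_t k[4] = {seed, a, b, c}, ctr[4] = {counter, 0u, 0u, 0u}, o[4];
  threefry4x64_12(k, ctr, o);
  return u64_to_unit(o[slot]);
}

double tf_normal(uint64_t seed, uint64_t a, uint64_t b, uint64_t c,
                 uint64_t counter) {
  uint64_t k[4] = {seed, a, b, c}, ctr[4] = {counter, 0u, 0u, 0u}, o[4];
  threefry4x64_12(k, ctr, o);
  double u1 = 1.0 - u64_to_unit(o[0]);
  double u2 = u64_to_unit(o[1]);
  return std::sqrt(-2.0 * std::log(u1)) *
         std::cos(6.283185307179586 * u2);
}
}  // namespace

// [[Rcpp::export(name = ".gb_protocol_cpp")]]
List gb_protocol_cpp(NumericVector t_pre, NumericVector t_post,
                     NumericVector par, int n_trials, double seed,
                     double dt, double t_end, bool noise) {
  const double w_star = par[0], tc_delay = par[1], c_pre = par[2],
               c_post = par[3], tau_c = par[4], tau_w = par[5],
               gamma_p = par[6], gamma_d = par[7], theta_p = par[8],
               theta_d = par[9], sigma_pl = par[10];
  // calcium jump schedule: pre influx delayed by tc_delay
  std::vector<std::pair<double, double>> jumps;
  for (double t : t_pre) jumps.push_back({t + tc_delay, c_pre});
  for (double t : t_post) jumps.push_back({t, c_post});
  std::sort(jumps.begin(), jumps.end());

  int n_steps = (int)std::ceil(t_end / dt);
  // per-step: calcium at step start, from exact decay + jumps
  std::vector<double> hp(n_steps), hd(n_steps);
  {
    double c = 0.0, t_c = 0.0;
    size_t j = 0;
    for (int s = 0; s < n_steps; ++s) {
      double t = s * dt;
      while (j < jumps.size() && jumps[j].first <= t) {
        c *= std::exp(-(jumps[j].first - t_c) / tau_c);
        c += jumps[j].second;
        t_c = jumps[j].first;
        ++j;
      }
      double c_now = c * std::exp(-(t - t_c) / tau_c);
      hp[s] = c_now >= theta_p ? 1.0 : 0.0;
      hd[s] = c_now >= theta_d ? 1.0 : 0.0;
    }
  }
  NumericVector w_start(n_trials), w_end(n_trials);
  uint64_t sd = (uint64_t)seed;
  double sqdt = std::sqrt(dt);
  for (int tr = 0; tr < n_trials; ++tr) {
    // initial weight drawn from {0, 1} with equal probability
    double w0 = tf_u01(sd, (uint64_t)tr, 0u, 0u, 0u, 0) < 0.5 ? 0.0 : 1.0;
    double w = w0;
    for (int s = 0; s < n_steps; ++s) {
      double drift = -w * (1.0 - w) * (w_star - w) +
                     gamma_p * (1.0 - w) * hp[s] - gamma_d * w * hd[s];
      w += drift * dt / tau_w;
      double act = hp[s] + hd[s];
      if (noise && act > 0.0) {
        double z = tf_normal(sd, (uint64_t)tr, 1u, 0u, (uint64_t)(s + 1));
        w += sigma_pl * std::sqrt(act / tau_w) * sqdt * z;
      }
    }
    w_start[tr] = w0;
    w_end[tr] = w;
  }
  return List::create(_["w_start"] = w_start, _["w_end"] = w_end);
}
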