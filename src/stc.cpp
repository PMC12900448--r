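// Single-synapse simulator for the two-phase (early/late) plasticity model:
// calcium-driven early-phase weight h with threshold-gated noise, synaptic
// tag, protein pool p, late-phase weight z, and an LIF postsynaptic neuron
// driven by the synapse through an exponential current plus white-noise
// background current. Fixed-dt Euler-Maruyama; spike times aligned to the
// step grid.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

void threefry4x64_12(const uint64_t key[4], const uint64_t ctr[4],
                     uint64_t out[4]);
double u64_to_unit(uint64_t v);

static double tf_norm1(uint64_t seed, uint64_t a, uint64_t b, uint64_t c,
                       uint64_t counter) {
  uint64_t k[4] = {seed, a, b, c}, ctr[4] = {counter, 0u, 0u, 0u}, o[4];
  threefry4x64_12(k, ctr, o);
  double u1 = 1.0 - u64_to_unit(o[0]);
  double u2 = u64_to_unit(o[1]);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

// par: h0 tauh tauc gp gd thp thd cpre cpost tcdelay sigma taup pmax thpro
//      thtag fint tauz
// lif: vrest vreset vth taum rm tref tausyn
// bg:  I0 sigma_wn(nA sqrt(ms))
// [[Rcpp::export(name = ".stc_single_cpp")]]
List stc_single_cpp(NumericVector pre_times, NumericVector par,
                    NumericVector lif, NumericVector bg, double dt,
                    double t_start, double t_end, double seed, double cell,
                    bool plasticity_noise, bool bg_noise,
                    NumericVector state0, double step_offset,
                    double record_every) {
  const double h0 = par[0], tauh = par[1], tauc = par[2], gp = par[3],
               gd = par[4], thp = par[5], thd = par[6], cpre = par[7],
               cpost = par[8], tcdelay = par[9], sigma = par[10],
               taup = par[11], pmax = par[12], thpro = par[13],
               thtag = par[14], fint = par[15], tauz = par[16];
  const double vrest = lif[0], vreset = lif[1], vth = lif[2], taum = lif[3],
               rm = lif[4], tref = lif[5], tausyn = lif[6];
  const double bgI0 = bg[0], bgsig = bg[1];
  const uint64_t sd = (uint64_t)seed, cid = (uint64_t)cell;

  double h = state0[0], z = state0[1], c = state0[2], p = state0[3],
         V = state0[4], Isyn = state0[5], ref = state0[6];
  int n_steps = (int)std::llround((t_end - t_start) / dt);
  const double cap = taum / rm;              // nF
  const double dec_syn = std::exp(-dt / tausyn);
  const double dec_c = std::exp(-dt / tauc);
  const double sqdt = std::sqrt(dt);

  // delayed presynaptic calcium influx times
  std::vector<double> ca_times(pre_times.begin(), pre_times.end());
  for (double& t : ca_times) t += tcdelay;
  std::sort(ca_times.begin(), ca_times.end());
  size_t ca_i = 0, pre_i = 0;
  std::vector<double> pre_sorted(pre_times.begin(), pre_times.end());
  std::sort(pre_sorted.begin(), pre_sorted.end());
  while (ca_i < ca_times.size() && ca_times[ca_i] < t_start) ++ca_i;
  while (pre_i < pre_sorted.size() && pre_sorted[pre_i] < t_start) ++pre_i;

  std::vector<double> post_spikes;
  int rec_stride = record_every > 0 ? std::max(1, (int)(record_every / dt)) : 0;
  std::vector<double> rt, rh, rz, rc, rp, rv;
  double max_dev = std::abs(h - h0);

  for (int s = 0; s < n_steps; ++s) {
    double t = t_start + s * dt;
    uint64_t gstep = (uint64_t)(step_offset + s);
    // presynaptic events due in [t, t+dt): synaptic current + delayed Ca
    while (pre_i < pre_sorted.size() && pre_sorted[pre_i] < t + dt) {
      double w = h + h0 * z;
      Isyn += w * cap / tausyn;     // nA; time-integrated drive equals w mV
      ++pre_i;
    }
    while (ca_i < ca_times.size() && ca_times[ca_i] < t + dt) {
      c += cpre;
      ++ca_i;
    }
    // membrane
    bool spiked = false;
    if (ref > 0) {
      ref -= dt;
      V = vreset;
    } else {
      double drive = -(V - vrest) + rm * (Isyn + bgI0);
      V += drive * dt / taum;
      if (bg_noise)
        V += rm * bgsig * sqdt / taum * tf_norm1(sd, cid, 0u, 0u, gstep);
      if (V >= vth) {
        spiked = true;
        V = vreset;
        ref = tref;
        post_spikes.push_back(t + dt);
        c += cpost;                 // postsynaptic calcium, same step
      }
    }
    Isyn *= dec_syn;
    // early phase
    double hp = c >= thp ? 1.0 : 0.0;
    double hd = c >= thd ? 1.0 : 0.0;
    double drift = 0.1 * (h0 - h) + gp * (10.0 - h) * hp - gd * h * hd;
    h += drift * dt / tauh;
    if (plasticity_noise && hp + hd > 0.0) {
      h += sigma * std::sqrt((hp + hd) / tauh) * sqdt *
           tf_norm1(sd, cid, 1u, 0u, gstep);
    }
    if (h < 0.0) h = 0.0;
    if (h > 10.0) h = 10.0;
    double dev = std::abs(h - h0);
    if (dev > max_dev) max_dev = dev;
    // protein pool (single synapse: the sum is this synapse's deviation)
    p += dt / taup * (-p + pmax * (dev >= thpro ? 1.0 : 0.0));
    // late phase
    double tag_up = (h - h0) >= thtag ? 1.0 : 0.0;
    double tag_dn = (h0 - h) >= thtag ? 1.0 : 0.0;
    z += dt / tauz * (p * fint * (1.0 - z) * tag_up -
                      p * fint * (z + 0.5) * tag_dn);
    c *= dec_c;
    if (rec_stride && s % rec_stride == 0) {
      rt.push_back(t + dt); rh.push_back(h); rz.push_back(z);
      rc.push_back(c); rp.push_back(p); rv.push_back(V);
    }
    (void)spiked;
  }
  NumericVector state = NumericVector::create(h, z, c, p, V, Isyn,
                                              ref > 0 ? ref : 0.0);
  return List::create(
    _["state"] = state, _["post_spikes"] = wrap(post_spikes),
    _["max_dev"] = max_dev,
    _["trace"] = DataFrame::create(_["t"] = wrap(rt), _["h"] = wrap(rh),
                                   _["z"] = wrap(rz), _["c"] = wrap(rc),
                                   _["p"] = wrap(rp), _["v"] = wrap(rv)));
}
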