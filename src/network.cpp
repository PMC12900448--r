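// Recurrent-network engine: LIF neurons with exponential current synapses
// and delayed delivery, plastic excitatory-to-excitatory synapses following
// the two-phase (early/late) calcium model, static synapses elsewhere,
// white-noise background current, and windowed Poisson stimulation. The
// whole state (including delivery ring buffers and the global step counter
// feeding the counter-based noise streams) is passed in and returned, so a
// run can be split at any phase boundary and resumed bit-identically.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

void threefry4x64_12(const uint64_t key[4], const uint64_t ctr[4],
                     uint64_t out[4]);
double u64_to_unit(uint64_t v);

static inline void tf_u2(uint64_t seed, uint64_t a, uint64_t b, uint64_t c,
                         uint64_t counter, double& u1, double& u2) {
  uint64_t k[4] = {seed, a, b, c}, ctr[4] = {counter, 0u, 0u, 0u}, o[4];
  threefry4x64_12(k, ctr, o);
  u1 = u64_to_unit(o[0]);
  u2 = u64_to_unit(o[1]);
}

static inline double tf_norm1(uint64_t seed, uint64_t a, uint64_t b,
                              uint64_t c, uint64_t counter) {
  double u1, u2;
  tf_u2(seed, a, b, c, counter, u1, u2);
  return std::sqrt(-2.0 * std::log(1.0 - u1)) *
         std::cos(6.283185307179586 * u2);
}

// [[Rcpp::export(name = ".stc_network_cpp")]]
List stc_network_cpp(List net, List state, List phase) {
  // -- network structure (0-based indices) --
  const int n = as<int>(net["n"]);
  IntegerVector s_ptr = net["s_ptr"];      // static synapses, CSR by source
  IntegerVector s_dst = net["s_dst"];
  NumericVector s_w = net["s_w"];          // signed weight, mV
  IntegerVector p_ptr = net["p_ptr"];      // plastic synapses, CSR by source
  IntegerVector p_idx = net["p_idx"];      // synapse id sorted by source
  IntegerVector p_dst = net["p_dst"];      // per synapse target
  IntegerVector t_ptr = net["t_ptr"];      // plastic synapses, CSR by target
  IntegerVector t_idx = net["t_idx"];
  const int n_plast = p_dst.size();
  List par = net["par"];
  const double dt = as<double>(par["dt"]);
  const double vrest = as<double>(par["v_rest"]),
               vreset = as<double>(par["v_reset"]),
               vth = as<double>(par["v_thresh"]),
               taum = as<double>(par["tau_m"]), rm = as<double>(par["r_m"]),
               tref = as<double>(par["t_ref"]),
               tausyn = as<double>(par["tau_syn"]);
  const int delay_steps = as<int>(par["delay_steps"]);
  const int delay_steps_inh = as<int>(par["delay_steps_inh"]);
  const int n_exc = as<int>(par["n_exc"]);
  const double h0 = as<double>(par["h0"]), tauh = as<double>(par["tau_h"]),
               tauc = as<double>(par["tau_c"]), gp = as<double>(par["gamma_p"]),
               gd = as<double>(par["gamma_d"]), thp = as<double>(par["theta_p"]),
               thd = as<double>(par["theta_d"]),
               cpre = as<double>(par["c_pre"]),
               cpost = as<double>(par["c_post"]),
               sigma = as<double>(par["sigma_pl"]),
               taup = as<double>(par["tau_p"]), pmax = as<double>(par["p_max"]),
               thpro = as<double>(par["theta_pro"]),
               thtag = as<double>(par["theta_tag"]),
               fint = as<double>(par["f_int"]), tauz = as<double>(par["tau_z"]);
  const int tc_steps = as<int>(par["tc_delay_steps"]);
  const double gain = as<double>(par["weight_gain"]);
  const double cmorpho = as<double>(par["c_morpho"]);
  const double bgI0 = as<double>(par["bg_i0"]),
               bgsig = as<double>(par["bg_sigma"]);
  const bool pl_noise = as<bool>(par["plasticity_noise"]);
  const bool plastic_on = as<bool>(par["plasticity_on"]);
  const uint64_t seed = (uint64_t)as<double>(par["seed"]);
  const double cap = taum / rm;

  // -- mutable state --
  NumericVector V = clone(as<NumericVector>(state["v"]));
  NumericVector ref = clone(as<NumericVector>(state["ref_left"]));
  NumericVector Isyn = clone(as<NumericVector>(state["i_syn"]));
  NumericVector h = clone(as<NumericVector>(state["h"]));
  NumericVector z = clone(as<NumericVector>(state["z"]));
  NumericVector ca = clone(as<NumericVector>(state["c"]));
  NumericVector pool = clone(as<NumericVector>(state["p"]));
  NumericMatrix ring = clone(as<NumericMatrix>(state["ring"]));  // n x L
  List ca_ring_in = state["ca_ring"];
  int ring_pos = as<int>(state["ring_pos"]);
  double step0 = as<double>(state["step"]);
  const int L = ring.ncol();
  const int Lc = ca_ring_in.size();
  std::vector<std::vector<int>> ca_ring(Lc);
  for (int i = 0; i < Lc; ++i) {
    IntegerVector v = ca_ring_in[i];
    ca_ring[i].assign(v.begin(), v.end());
  }
  int ca_pos = as<int>(state["ca_pos"]);

  // -- phase schedule --
  const double t_start = as<double>(phase["t_start"]);
  const double t_end = as<double>(phase["t_end"]);
  NumericMatrix stim = phase["stim"];      // rows: t0 t1 rate_hz w_mv
  List stim_targets = phase["stim_targets"];
  std::vector<std::vector<int>> stgt(stim.nrow());
  for (int i = 0; i < stim.nrow(); ++i) {
    IntegerVector v = stim_targets[i];
    stgt[i].assign(v.begin(), v.end());
  }
  const bool record = as<bool>(phase["record_spikes"]);

  const double dec_syn = std::exp(-dt / tausyn);
  const double dec_c = std::exp(-dt / tauc);
  const double sqdt = std::sqrt(dt);
  int n_steps = (int)std::llround((t_end - t_start) / dt);

  std::vector<double> spike_t;
  std::vector<int> spike_gid;
  std::vector<int> spiked;
  std::vector<double> sumdev(n);

  for (int s = 0; s < n_steps; ++s) {
    double t = t_start + s * dt;
    uint64_t gstep = (uint64_t)(step0 + s);
    // deliver due synaptic input
    for (int i = 0; i < n; ++i) {
      Isyn[i] += ring(i, ring_pos) * cap / tausyn;
      ring(i, ring_pos) = 0.0;
    }
    // deliver due delayed presynaptic calcium
    for (int sid : ca_ring[ca_pos]) ca[sid] += cpre;
    ca_ring[ca_pos].clear();
    // windowed Poisson stimulation (per target, thinned per step)
    for (int wi = 0; wi < stim.nrow(); ++wi) {
      if (t >= stim(wi, 0) && t < stim(wi, 1)) {
        double pr = stim(wi, 2) * dt / 1000.0;
        double wmv = stim(wi, 3);
        // expected arrivals per step may exceed one for strong drive:
        // deliver the integer part deterministically, the remainder as a
        // Bernoulli arrival
        double base = std::floor(pr);
        double frac = pr - base;
        for (int gid : stgt[wi]) {
          double u1, u2;
          tf_u2(seed, (uint64_t)gid, 3u, (uint64_t)wi, gstep, u1, u2);
          double arrivals = base + (u1 < frac ? 1.0 : 0.0);
          if (arrivals > 0.0) Isyn[gid] += arrivals * wmv * cap / tausyn;
        }
      }
    }
    // membrane update and spike detection
    spiked.clear();
    for (int i = 0; i < n; ++i) {
      if (ref[i] > 0) {
        ref[i] -= dt;
        V[i] = vreset;
      } else {
        V[i] += (-(V[i] - vrest) + rm * (Isyn[i] + bgI0)) * dt / taum;
        if (bgsig > 0)
          V[i] += rm * bgsig * sqdt / taum *
                  tf_norm1(seed, (uint64_t)i, 0u, 0u, gstep);
        if (V[i] >= vth) {
          V[i] = vreset;
          ref[i] = tref;
          spiked.push_back(i);
          if (record) {
            spike_t.push_back(t + dt);
            spike_gid.push_back(i);
          }
        }
      }
      Isyn[i] *= dec_syn;
    }
    // spike effects: delayed delivery plus calcium bookkeeping
    int dslot = (ring_pos + delay_steps) % L;
    int cslot = (ca_pos + tc_steps) % Lc;
    for (int src : spiked) {
      // inhibitory sources deliver with their own (shorter) delay
      int sslot = src >= n_exc ? (ring_pos + delay_steps_inh) % L : dslot;
      for (int k = s_ptr[src]; k < s_ptr[src + 1]; ++k)
        ring(s_dst[k], sslot) += s_w[k] * gain;
      for (int k = p_ptr[src]; k < p_ptr[src + 1]; ++k) {
        int sid = p_idx[k];
        ring(p_dst[sid], dslot) += (h[sid] + h0 * z[sid]) * gain * cmorpho;
        ca_ring[cslot].push_back(sid);
      }
      // postsynaptic calcium at plastic synapses targeting the spiker
      for (int k = t_ptr[src]; k < t_ptr[src + 1]; ++k)
        ca[t_idx[k]] += cpost;
    }
    // plasticity update
    if (plastic_on) {
      std::fill(sumdev.begin(), sumdev.end(), 0.0);
      for (int sid = 0; sid < n_plast; ++sid) {
        double cs = ca[sid];
        double hp = cs >= thp ? 1.0 : 0.0;
        double hd = cs >= thd ? 1.0 : 0.0;
        double hv = h[sid];
        if (hp + hd > 0.0) {
          hv += (0.1 * (h0 - hv) + gp * (10.0 - hv) * hp - gd * hv * hd) *
                dt / tauh;
          if (pl_noise)
            hv += sigma * std::sqrt((hp + hd) / tauh) * sqdt *
                  tf_norm1(seed, (uint64_t)sid, 1u, 0u, gstep);
          if (hv < 0.0) hv = 0.0;
          if (hv > 10.0) hv = 10.0;
        } else {
          hv += 0.1 * (h0 - hv) * dt / tauh;
        }
        h[sid] = hv;
        double dev = std::fabs(hv - h0);
        sumdev[p_dst[sid]] += dev;
        double pp = pool[p_dst[sid]];
        if (pp > 0.0) {
          double tag_up = (hv - h0) >= thtag ? 1.0 : 0.0;
          double tag_dn = (h0 - hv) >= thtag ? 1.0 : 0.0;
          if (tag_up + tag_dn > 0.0)
            z[sid] += dt / tauz * (pp * fint * (1.0 - z[sid]) * tag_up -
                                   pp * fint * (z[sid] + 0.5) * tag_dn);
        }
        ca[sid] = cs * dec_c;
      }
      for (int i = 0; i < n; ++i)
        pool[i] += dt / taup *
                   (-pool[i] + pmax * (sumdev[i] >= thpro ? 1.0 : 0.0));
    } else {
      for (int sid = 0; sid < n_plast; ++sid) ca[sid] *= dec_c;
    }
    ring_pos = (ring_pos + 1) % L;
    ca_pos = (ca_pos + 1) % Lc;
  }

  List ca_ring_out(Lc);
  for (int i = 0; i < Lc; ++i) ca_ring_out[i] = wrap(ca_ring[i]);
  List st = List::create(
    _["v"] = V, _["ref_left"] = ref, _["i_syn"] = Isyn, _["h"] = h,
    _["z"] = z, _["c"] = ca, _["p"] = pool, _["ring"] = ring,
    _["ca_ring"] = ca_ring_out, _["ring_pos"] = ring_pos,
    _["ca_pos"] = ca_pos, _["step"] = step0 + n_steps);
  return List::create(_["state"] = st, _["spike_t"] = wrap(spike_t),
                      _["spike_gid"] = wrap(spike_gid));
}
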