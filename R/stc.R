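#' Two-phase synapse with synaptic tagging and capture
#'
#' The synaptic-tagging-and-capture (STC) model of early- and late-phase
#' plasticity. The total weight `w = h + h0 z` consists of a fast,
#' calcium-driven early-phase weight `h` (mV) and a slow late-phase weight
#' `z` (dimensionless, normalized by `h0`). The early phase follows
#' `tau_h dh/dt = 0.1 (h0 - h) + gamma_p (10 mV - h) H[c - theta_p]
#'  - gamma_d h H[c - theta_d] + xi(t)`
#' with threshold-gated noise `xi`; calcium decays with `tau_c` and jumps by
#' `c_pre` (delayed by `tc_delay`) and `c_post` at pre-/postsynaptic spikes.
#' The synapse is tagged while `|h - h0| > theta_tag`; the late phase
#' `tau_z dz/dt = p f_int (1-z) H[(h-h0)-theta_tag]
#'  - p f_int (z+0.5) H[(h0-h)-theta_tag]`
#' changes only while the synapse is tagged and plasticity-related products
#' (PRPs) are available (`p > 0`). PRP synthesis in the owning neuron's pool
#' requires the summed early-phase change of its synapses to exceed
#' `theta_pro` (see [prp_step()]).
#'
#' @param params see [stc_params()].
#' @return An object of class `stc_synapse`.
#' @export
stc_synapse <- function(params = stc_params()) {
  structure(list(h = params$h0, z = 0, c = 0, t = 0, pending = numeric(0),
                 params = params),
            class = "stc_synapse")
}

#' Parameters of the tagging-and-capture model
#'
#' Defaults (times ms, weights mV): `h0 = 4.20075` (equal to
#' `0.5 gamma_p / (gamma_p + gamma_d) * 10 mV`), `tc_delay = 18.8`,
#' `c_pre = 1.0`, `c_post = 0.2758`, `tau_c = 48.8`, `tau_h = 688400`
#' (688.4 s), `tau_p = tau_z = 3.6e6` (60 min), `gamma_p = 1645.6`,
#' `gamma_d = 313.1`, `theta_p = 3.0`, `theta_d = 1.2`,
#' `sigma_pl = 2.90436` mV, `p_max = 10` umol/l, `theta_pro = 2.10037`
#' (`0.5 h0`), `theta_tag = 0.840149` (`0.2 h0`), `f_int = 0.1` l/umol.
#' With `in_vivo = TRUE` the calcium contributions are corrected by a factor
#' 0.6 (the network condition).
#'
#' @param in_vivo logical; apply the 0.6 calcium correction.
#' @param ... overrides.
#' @return Parameter list.
#' @export
stc_params <- function(in_vivo = FALSE, ...) {
  p <- list(h0 = 4.20075, tc_delay = 18.8, c_pre = 1.0, c_post = 0.2758,
            tau_c = 48.8, tau_h = 688400, tau_p = 3.6e6, tau_z = 3.6e6,
            gamma_p = 1645.6, gamma_d = 313.1, theta_p = 3.0, theta_d = 1.2,
            sigma_pl = 2.90436, p_max = 10.0, theta_pro = 2.10037,
            theta_tag = 0.840149, f_int = 0.1, h_max = 10.0)
  if (in_vivo) {
    p$c_pre <- p$c_pre * 0.6
    p$c_post <- p$c_post * 0.6
  }
  utils::modifyList(p, list(...))
}

#' Neuron and background-input defaults for the tagging-and-capture model
#'
#' LIF membrane (rest -65 mV, reset -70 mV, threshold -55 mV, tau 10 ms,
#' resistance 10 MOhm, refractory 2 ms), exponential synaptic current with
#' tau 5 ms, axonal delay 3 ms, and a white-noise background current of mean
#' 0.15 nA and standard deviation 0.05 nA sqrt(s). These membrane and input
#' constants are configuration, not printed model constants; the defaults
#' are documented choices producing sparse spontaneous activity (about 1 Hz)
#' with the default coupling strength.
#'
#' @param ... overrides.
#' @return Parameter list (`bg_sigma` is stored in nA sqrt(ms)).
#' @export
stc_neuron_defaults <- function(...) {
  utils::modifyList(
    list(v_rest = -65, v_reset = -70, v_thresh = -55, tau_m = 10, r_m = 10,
         t_ref = 2, tau_syn = 5, delay = 3, delay_inh = 1,
         bg_i0 = 0.15, bg_sigma = 0.05 * sqrt(1000)),
    list(...))
}

#' Register a spike at a tagging-and-capture synapse
#'
#' @param syn an [stc_synapse()].
#' @param t spike time (ms).
#' @param kind `"pre"` (schedules delayed calcium influx `c_pre` at
#'   `t + tc_delay`) or `"post"` (immediate influx `c_post`).
#' @return Updated synapse.
#' @export
stc_on_spike <- function(syn, t, kind = c("pre", "post")) {
  kind <- match.arg(kind)
  if (t < syn$t) stop("spike time regression")
  if (kind == "post") {
    syn <- .stc_advance_calcium(syn, t)
    syn$c <- syn$c + syn$params$c_post
  } else {
    syn$pending <- sort(c(syn$pending, t + syn$params$tc_delay))
  }
  syn
}

.stc_advance_calcium <- function(syn, t) {
  while (length(syn$pending) && syn$pending[1] <= t) {
    td <- syn$pending[1]
    syn$pending <- syn$pending[-1]
    syn$c <- syn$c * exp(-(td - syn$t) / syn$params$tau_c) + syn$params$c_pre
    syn$t <- td
  }
  syn$c <- syn$c * exp(-(t - syn$t) / syn$params$tau_c)
  syn$t <- t
  syn
}

#' One step of the tagging-and-capture synapse
#'
#' Euler-Maruyama step of the early-phase weight (noise active only while
#' calcium exceeds a threshold; `h` clipped to `[0, 10]` mV), Euler step of
#' the late-phase weight using the owning neuron's PRP concentration, and
#' analytic calcium decay with exact handling of scheduled delayed influx.
#' The returned `dev = |h - h0|` is the synapse's contribution to the
#' neuron-level PRP synthesis threshold sum.
#'
#' @param syn an [stc_synapse()].
#' @param pool a [prp_pool()] (its concentration `p` drives the late phase).
#' @param dt step size (ms, > 0).
#' @param stream optional [noise_stream()]; `NULL` disables the noise term.
#' @return List `(syn, dev)`.
#' @export
stc_step <- function(syn, pool, dt, stream = NULL) {
  if (dt <= 0) stop("dt must be positive")
  p <- syn$params
  hp <- as.numeric(syn$c >= p$theta_p)
  hd <- as.numeric(syn$c >= p$theta_d)
  h <- syn$h
  drift <- 0.1 * (p$h0 - h) + p$gamma_p * (p$h_max - h) * hp -
    p$gamma_d * h * hd
  h <- h + drift * dt / p$tau_h
  if (!is.null(stream) && (hp + hd) > 0)
    h <- h + p$sigma_pl * sqrt((hp + hd) / p$tau_h) * sqrt(dt) *
      .stream_normal(stream)
  h <- min(p$h_max, max(0, h))
  tag_up <- as.numeric((h - p$h0) >= p$theta_tag)
  tag_dn <- as.numeric((p$h0 - h) >= p$theta_tag)
  syn$z <- syn$z + dt / p$tau_z * (pool$p * p$f_int * (1 - syn$z) * tag_up -
                                     pool$p * p$f_int * (syn$z + 0.5) * tag_dn)
  syn$h <- h
  syn <- .stc_advance_calcium(syn, syn$t + dt)
  list(syn = syn, dev = abs(h - p$h0))
}

#' Total weight of a tagging-and-capture synapse
#'
#' @param syn an [stc_synapse()].
#' @return `h + h0 z` (mV).
#' @export
stc_weight <- function(syn) syn$h + syn$params$h0 * syn$z

#' Plasticity-related product pool of a neuron
#'
#' @param params see [stc_params()] (`tau_p`, `p_max`, `theta_pro`).
#' @param p initial concentration (umol/l).
#' @return An object of class `prp_pool`.
#' @export
prp_pool <- function(params = stc_params(), p = 0) {
  structure(list(p = p, params = params), class = "prp_pool")
}

#' One step of the protein pool
#'
#' `tau_p dp/dt = -p + p_max H[sum_dev - theta_pro]`, integrated exactly
#' over the step (linear dynamics with a forcing that is constant within the
#' step); `sum_dev` is the summed early-phase weight change
#' `sum |h - h0|` over the neuron's synapses.
#'
#' @param pool a [prp_pool()].
#' @param sum_dev summed early-phase deviation (mV).
#' @param dt step size (ms, > 0).
#' @return Updated pool with `p` in `[0, p_max]`.
#' @export
prp_step <- function(pool, sum_dev, dt) {
  if (dt <= 0) stop("dt must be positive")
  pr <- pool$params
  target <- if (sum_dev >= pr$theta_pro) pr$p_max else 0
  pool$p <- target + (pool$p - target) * exp(-dt / pr$tau_p)
  pool
}

# -- stimulation protocols ---------------------------------------------------

#' Presynaptic spike times of the classical plasticity-induction protocols
#'
#' The four standard induction protocols, as commonly parameterized for this
#' model family (the exact pulse parameters are configuration presets, not
#' printed constants of the model): strong tetanus `STET` (three 1-s bursts
#' of 100 Hz, 10 min apart), weak tetanus `WTET` (one 0.2-s burst of
#' 100 Hz), strong low-frequency stimulation `SLFS` (900 bursts at 1 Hz,
#' each burst three spikes at 20 Hz), and weak low-frequency stimulation
#' `WLFS` (900 single pulses at 1 Hz).
#'
#' @param name protocol name.
#' @return List with `times` (ms) and `t_end` (end of stimulation phase, ms).
#' @export
stc_protocol_times <- function(name = c("STET", "WTET", "SLFS", "WLFS")) {
  name <- match.arg(name)
  switch(name,
    STET = {
      t <- as.vector(outer(seq(0, 990, by = 10), c(0, 600e3, 1200e3), "+"))
      list(times = sort(t), t_end = 1203e3)
    },
    WTET = list(times = seq(0, 190, by = 10), t_end = 3e3),
    SLFS = {
      t <- as.vector(outer(c(0, 50, 100), seq(0, 899e3, by = 1e3), "+"))
      list(times = sort(t), t_end = 902e3)
    },
    WLFS = list(times = seq(0, 899e3, by = 1e3), t_end = 902e3))
}

#' Run one induction protocol at a single synapse
#'
#' Simulates a single tagging-and-capture synapse onto an LIF neuron through
#' the full stimulation phase (fixed-dt Euler-Maruyama with counter-based
#' noise), then fast-forwards the slow variables (early-phase relaxation,
#' late phase, protein pool) to `t_total`. Returns the weight trace and the
#' threshold-crossing summary.
#'
#' @param name protocol name, see [stc_protocol_times()].
#' @param seed global seed.
#' @param trial trial index (selects independent noise streams).
#' @param params [stc_params()] (the single-synapse condition: no in vivo
#'   calcium correction).
#' @param neuron [stc_neuron_defaults()].
#' @param dt integration step during stimulation (ms).
#' @param t_total total biological time (ms); default 8 h.
#' @param noise logical, plasticity and background noise on/off.
#' @param record_every trace sampling interval (ms; 0 disables).
#' @return List with `trace` (data frame `t, h, z, c, p, v`), `h_end`,
#'   `z_end`, `p_end`, `w_end`, `max_dev`, `crossed_tag`, `crossed_pro`.
#' @export
stc_protocol <- function(name, seed = 1, trial = 0, params = stc_params(),
                         neuron = stc_neuron_defaults(), dt = 0.5,
                         t_total = 8 * 3600e3, noise = TRUE,
                         record_every = 1000) {
  prot <- stc_protocol_times(name)
  par_vec <- as.numeric(unlist(params[c(
    "h0", "tau_h", "tau_c", "gamma_p", "gamma_d", "theta_p", "theta_d",
    "c_pre", "c_post", "tc_delay", "sigma_pl", "tau_p", "p_max",
    "theta_pro", "theta_tag", "f_int", "tau_z")]))
  lif_vec <- as.numeric(unlist(neuron[c(
    "v_rest", "v_reset", "v_thresh", "tau_m", "r_m", "t_ref", "tau_syn")]))
  bg_vec <- c(neuron$bg_i0, neuron$bg_sigma)
  state0 <- c(params$h0, 0, 0, 0, neuron$v_rest, 0, 0)
  res <- .stc_single_cpp(prot$times + 100, par_vec, lif_vec, bg_vec, dt,
                         0, prot$t_end, seed, trial, noise, noise,
                         state0, 0, record_every)
  st <- res$state
  ff <- stc_fast_forward(h = st[1], z = st[2], p = st[4],
                         t_span = t_total - prot$t_end, params = params)
  list(trace = res$trace, post_spikes = res$post_spikes,
       h_end = ff$h, z_end = ff$z, p_end = ff$p,
       w_end = ff$h + params$h0 * ff$z,
       h_after_stim = st[1], z_after_stim = st[2], p_after_stim = st[4],
       max_dev = res$max_dev,
       crossed_tag = res$max_dev >= params$theta_tag,
       crossed_pro = res$max_dev >= params$theta_pro)
}

#' Fast-forward integration of the slow plasticity variables
#'
#' Coarse-timestep integration for quiescent phases: no spiking and no
#' calcium dynamics are simulated; only the early-phase relaxation towards
#' `h0` (exact exponential), PRP synthesis/decay, and the late phase are
#' advanced. Inputs may be vectors (one entry per synapse) with a scalar or
#' per-neuron pool handled by the caller; here `p` is the pool seen by the
#' given synapses and the synthesis indicator uses `sum(|h - h0|)`.
#'
#' @param h,z early- and late-phase weights (vectors of equal length).
#' @param p PRP concentration (scalar pool).
#' @param t_span time to advance (ms).
#' @param params [stc_params()].
#' @param dt_ff coarse step (ms).
#' @return List `h`, `z`, `p` after `t_span`.
#' @export
stc_fast_forward <- function(h, z, p, t_span, params = stc_params(),
                             dt_ff = 1000) {
  if (t_span <= 0) return(list(h = h, z = z, p = p))
  pr <- params
  n_steps <- ceiling(t_span / dt_ff)
  dec_h <- exp(-0.1 * dt_ff / pr$tau_h)
  dec_p <- exp(-dt_ff / pr$tau_p)
  for (k in seq_len(n_steps)) {
    dev <- abs(h - pr$h0)
    target <- if (sum(dev) >= pr$theta_pro) pr$p_max else 0
    tag_up <- as.numeric((h - pr$h0) >= pr$theta_tag)
    tag_dn <- as.numeric((pr$h0 - h) >= pr$theta_tag)
    z <- z + dt_ff / pr$tau_z * (p * pr$f_int * (1 - z) * tag_up -
                                   p * pr$f_int * (z + 0.5) * tag_dn)
    p <- target + (p - target) * dec_p
    h <- pr$h0 + (h - pr$h0) * dec_h
  }
  list(h = h, z = z, p = p)
}

#' Basic single-synapse run with explicit presynaptic spike times
#'
#' @param pre_times presynaptic spike times (ms).
#' @param t_end simulated time (ms).
#' @param seed,trial stream selectors.
#' @param params,neuron,dt,noise,record_every as in [stc_protocol()].
#' @return As the kernel: `state`, `post_spikes`, `max_dev`, `trace`.
#' @export
stc_single_run <- function(pre_times, t_end, seed = 1, trial = 0,
                           params = stc_params(),
                           neuron = stc_neuron_defaults(), dt = 0.5,
                           noise = TRUE, record_every = 10) {
  par_vec <- as.numeric(unlist(params[c(
    "h0", "tau_h", "tau_c", "gamma_p", "gamma_d", "theta_p", "theta_d",
    "c_pre", "c_post", "tc_delay", "sigma_pl", "tau_p", "p_max",
    "theta_pro", "theta_tag", "f_int", "tau_z")]))
  lif_vec <- as.numeric(unlist(neuron[c(
    "v_rest", "v_reset", "v_thresh", "tau_m", "r_m", "t_ref", "tau_syn")]))
  bg_vec <- c(neuron$bg_i0, neuron$bg_sigma)
  state0 <- c(params$h0, 0, 0, 0, neuron$v_rest, 0, 0)
  .stc_single_cpp(pre_times, par_vec, lif_vec, bg_vec, dt, 0, t_end,
                  seed, trial, noise, noise, state0, 0, record_every)
}
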