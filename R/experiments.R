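#' Poisson-driven STDP experiment at a single synapse
#'
#' One LIF neuron receives an excitatory, conductance-based synapse under
#' pair-based STDP and a static inhibitory synapse (stabilizing the
#' dynamics), each driven by an independent Poisson source. Postsynaptic
#' spikes reach the plastic mechanism through the postsynaptic-spike
#' dispatch hook; a second co-located mechanism (an event counter) receives
#' every event as well, demonstrating fan-out delivery to multiple
#' mechanisms without per-connection labels.
#'
#' The synaptic and input constants (rates, reversal potentials, synaptic
#' time constant) are configuration with documented defaults.
#'
#' @param duration simulated time (ms).
#' @param rate_exc,rate_inh Poisson rates (Hz).
#' @param params [stdp_params()].
#' @param w_inh inhibitory conductance (uS).
#' @param e_exc,e_inh synaptic reversal potentials (mV).
#' @param tau_syn synaptic time constant (ms).
#' @param neuron a [lif_neuron()].
#' @param dt step (ms).
#' @param seed global seed.
#' @return List with the weight trace (`t`, `w`), postsynaptic spike times,
#'   the final synapse, and the per-mechanism delivery counters.
#' @export
run_stdp_experiment <- function(duration = 10000, rate_exc = 25,
                                rate_inh = 25,
                                params = stdp_params("detailed"),
                                w_inh = 1.0, e_exc = 0, e_inh = -80,
                                tau_syn = 5, neuron = lif_neuron(),
                                dt = 0.1, seed = 1) {
  pre_exc <- poisson_spikes(rate_exc, 0, duration,
                            noise_stream(seed = seed, mechanism = 1))
  pre_inh <- poisson_spikes(rate_inh, 0, duration,
                            noise_stream(seed = seed, mechanism = 2))
  syn <- stdp_synapse(params)
  counter <- list(n_pre = 0L, n_post = 0L)
  g_exc <- 0; g_inh <- 0
  dec <- exp(-dt / tau_syn)
  n_steps <- round(duration / dt)
  ie <- 1L; ii <- 1L
  t_post <- numeric(0)
  rec_t <- numeric(0); rec_w <- numeric(0)
  cell <- list(mechanisms = list(
    stdp = list(on_post = function(mech, t) mech),   # filled per event below
    count = list(on_post = function(mech, t) mech)))
  for (s in seq_len(n_steps)) {
    t <- s * dt
    while (ie <= length(pre_exc) && pre_exc[ie] < t) {
      syn <- stdp_on_spike(syn, t, "pre")
      counter$n_pre <- counter$n_pre + 1L
      g_exc <- g_exc + stdp_conductance(syn)
      ie <- ie + 1L
    }
    while (ii <= length(pre_inh) && pre_inh[ii] < t) {
      g_inh <- g_inh + w_inh
      ii <- ii + 1L
    }
    i_syn <- g_exc * (e_exc - neuron$v) + g_inh * (e_inh - neuron$v)
    st <- lif_step(neuron, list(current = i_syn), dt)
    neuron <- st$neuron
    if (st$spiked) {
      t_post <- c(t_post, t)
      # postsynaptic-spike dispatch: both mechanisms observe the spike
      cell$mechanisms$stdp$on_post <- function(mech, tt) {
        syn <<- stdp_on_spike(syn, tt, "post")
        mech
      }
      cell$mechanisms$count$on_post <- function(mech, tt) {
        counter$n_post <<- counter$n_post + 1L
        mech
      }
      cell <- post_event_dispatch(cell, t)
    }
    g_exc <- g_exc * dec
    g_inh <- g_inh * dec
    if (s %% round(10 / dt) == 0) {
      rec_t <- c(rec_t, t)
      rec_w <- c(rec_w, syn$w)
    }
  }
  list(trace = data.frame(t = rec_t, w = rec_w), t_post = t_post,
       synapse = syn, counters = counter)
}
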