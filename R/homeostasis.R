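#' Spike-driven homeostatic synapse
#'
#' The weight of the plastic synapse changes by `dw_plus` on every
#' presynaptic spike and by `dw_minus` (negative) on every postsynaptic
#' spike, and is clipped to `[0, w_max]` after every update. With
#' `dw_plus = -dw_minus` the stationary postsynaptic rate equals the
#' presynaptic rate of the plastic input (every imbalance moves the weight
#' against it), which regulates the neuron towards the plastic input's rate.
#'
#' @param params see [homeo_params()].
#' @return An object of class `homeo_synapse`.
#' @export
homeo_synapse <- function(params = homeo_params()) {
  structure(list(w = params$w_init, params = params),
            class = "homeo_synapse")
}

#' Homeostasis parameters
#'
#' Defaults: `w_init = 0 nA`, `w_max = 5 nA`, `dw_plus = 0.35 nA`,
#' `dw_minus = -0.35 nA`, static companion weight `w_varying = 3.5 nA`.
#'
#' @param ... overrides.
#' @return Parameter list.
#' @export
homeo_params <- function(...) {
  utils::modifyList(
    list(w_init = 0, w_max = 5, dw_plus = 0.35, dw_minus = -0.35,
         w_varying = 3.5),
    list(...))
}

#' Apply a spike to a homeostatic synapse
#'
#' @param syn a [homeo_synapse()].
#' @param kind `"pre"` or `"post"`.
#' @return Updated synapse with weight clipped to `[0, w_max]`.
#' @export
homeo_on_spike <- function(syn, kind = c("pre", "post")) {
  kind <- match.arg(kind)
  dw <- if (kind == "pre") syn$params$dw_plus else syn$params$dw_minus
  syn$w <- min(syn$params$w_max, max(0, syn$w + dw))
  syn
}

#' Spike-driven homeostasis experiment
#'
#' One LIF neuron driven by two Poisson inputs through current-based delta
#' synapses: a plastic input at a fixed rate whose weight follows
#' [homeo_on_spike()], and a static input (`w_varying`) whose rate steps
#' through a schedule that includes a silent period. Simulated
#' event-drivenly: between input events the potential decays exactly, spikes
#' can only occur at event times (delta synapses), and each input spike of
#' weight `w` (nA) depolarizes by `w * jump_scale` mV.
#'
#' @param duration total simulated time (ms).
#' @param rate_plastic fixed rate of the plastic input (Hz).
#' @param schedule data frame `t0`, `t1` (ms), `rate` (Hz) for the
#'   varying-rate static input; defaults to the bundled 60-s schedule with a
#'   silent period from 20 s to 30 s.
#' @param params [homeo_params()].
#' @param neuron a [lif_neuron()]; the default neuron (threshold 4 mV above
#'   rest, reset at rest) puts the 50-Hz homeostatic set point inside the
#'   attainable range for the default weights: the static input alone stays
#'   below the set point at its maximal scheduled rate, while the plastic
#'   input can exceed it with the weight well inside `[0, w_max]`.
#' @param jump_scale depolarization per unit weight (mV/nA).
#' @param plasticity if `FALSE` the plastic weight is frozen at `w_init`
#'   (control condition: the output rate then follows the varying input).
#' @param stream_pre,stream_var noise streams for the two Poisson inputs.
#' @return List with spike times (`t_post`, ms), input trains, weight trace
#'   (`t`, `w`), and `rate_fn(t0, t1)` returning the mean output rate on a
#'   window.
#' @export
run_homeostasis_experiment <- function(duration = 60000,
                                       rate_plastic = 50,
                                       schedule = homeo_default_schedule(),
                                       params = homeo_params(),
                                       neuron = lif_neuron(v_rest = -65,
                                                           v_reset = -65,
                                                           v_thresh = -61,
                                                           tau_m = 10,
                                                           t_ref = 2),
                                       jump_scale = 1.0,
                                       plasticity = TRUE,
                                       stream_pre = noise_stream(seed = 1, mechanism = 1),
                                       stream_var = noise_stream(seed = 1, mechanism = 2)) {
  pre <- poisson_spikes(rate_plastic, 0, duration, stream_pre)
  var_times <- numeric(0)
  for (k in seq_len(nrow(schedule))) {
    if (schedule$rate[k] > 0 && schedule$t0[k] < duration)
      var_times <- c(var_times,
                     poisson_spikes(schedule$rate[k], schedule$t0[k],
                                    min(schedule$t1[k], duration), stream_var))
  }
  ev_t <- c(pre, var_times)
  ev_kind <- c(rep(1L, length(pre)), rep(2L, length(var_times)))
  ord <- order(ev_t)
  ev_t <- ev_t[ord]; ev_kind <- ev_kind[ord]
  syn <- homeo_synapse(params)
  v <- neuron$v_rest
  t_now <- 0
  ref_until <- -Inf
  t_post <- numeric(0)
  wt_t <- numeric(length(ev_t)); wt_w <- numeric(length(ev_t))
  n_post <- 0L
  for (i in seq_along(ev_t)) {
    t <- ev_t[i]
    v <- neuron$v_rest + (v - neuron$v_rest) * exp(-(t - t_now) / neuron$tau_m)
    t_now <- t
    if (t >= ref_until) {
      if (ev_kind[i] == 1L) {
        if (plasticity) syn <- homeo_on_spike(syn, "pre")
        v <- v + syn$w * jump_scale
      } else {
        v <- v + params$w_varying * jump_scale
      }
      if (v >= neuron$v_thresh) {
        n_post <- n_post + 1L
        t_post <- c(t_post, t)
        if (plasticity) syn <- homeo_on_spike(syn, "post")
        v <- neuron$v_reset
        ref_until <- t + neuron$t_ref
      }
    } else if (ev_kind[i] == 1L && plasticity) {
      # presynaptic weight updates still happen during refractoriness
      syn <- homeo_on_spike(syn, "pre")
    }
    wt_t[i] <- t; wt_w[i] <- syn$w
  }
  rate_fn <- function(t0, t1) sum(t_post >= t0 & t_post < t1) / (t1 - t0) * 1000
  list(t_post = t_post, t_pre = pre, t_varying = var_times,
       weight = data.frame(t = wt_t, w = wt_w), rate_fn = rate_fn,
       schedule = schedule, duration = duration)
}

#' Default varying-input schedule
#'
#' Six 10-s stages at 40, 70, 0, 55, 25 and 60 Hz; the third stage is the
#' silent period during which the plastic weight can only partially
#' compensate (it is capped at `w_max`).
#'
#' @return Data frame with columns `t0`, `t1` (ms) and `rate` (Hz).
#' @export
homeo_default_schedule <- function() {
  data.frame(t0 = seq(0, 50000, by = 10000),
             t1 = seq(10000, 60000, by = 10000),
             rate = c(40, 70, 0, 55, 25, 60))
}
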