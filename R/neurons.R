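#' Leaky integrate-and-fire neuron
#'
#' Standard LIF dynamics `tau_m dV/dt = -(V - v_rest) + R I(t)` with hard
#' threshold, reset, and absolute refractory period. Spike times are aligned
#' to the step grid: a threshold crossing is registered at the end of the
#' step in which it occurs.
#'
#' @param v_rest resting potential (mV).
#' @param v_reset reset potential (mV).
#' @param v_thresh spike threshold (mV).
#' @param tau_m membrane time constant (ms).
#' @param r_m membrane resistance (MOhm; MOhm x nA = mV).
#' @param t_ref absolute refractory period (ms).
#' @return An object of class `lif_neuron`.
#' @export
lif_neuron <- function(v_rest = -65, v_reset = -70, v_thresh = -55,
                       tau_m = 10, r_m = 10, t_ref = 2) {
  structure(list(v = v_rest, v_rest = v_rest, v_reset = v_reset,
                 v_thresh = v_thresh, tau_m = tau_m, r_m = r_m,
                 t_ref = t_ref, ref_left = 0),
            class = "lif_neuron")
}

#' One step of LIF dynamics
#'
#' Exponential-Euler update with a constant input current over the step plus
#' optional instantaneous potential jumps (current-based delta synapses).
#' During the refractory period the potential is clamped at reset and all
#' input is discarded, so no spike can be emitted regardless of input size.
#'
#' @param neuron a [lif_neuron()].
#' @param input list with optional elements `current` (nA, constant over the
#'   step) and `jump` (mV, added instantaneously at the start of the step).
#' @param dt step size (ms, > 0).
#' @return List `(neuron, spiked)`.
#' @export
lif_step <- function(neuron, input = list(), dt) {
  if (dt <= 0) stop("dt must be positive")
  spiked <- FALSE
  if (neuron$ref_left > 0) {
    neuron$ref_left <- max(0, neuron$ref_left - dt)
    neuron$v <- neuron$v_reset
  } else {
    i_in <- if (is.null(input$current)) 0 else input$current
    jump <- if (is.null(input$jump)) 0 else input$jump
    vinf <- neuron$v_rest + neuron$r_m * i_in
    decay <- exp(-dt / neuron$tau_m)
    neuron$v <- vinf + (neuron$v + jump - vinf) * decay
    if (neuron$v >= neuron$v_thresh) {
      spiked <- TRUE
      neuron$v <- neuron$v_reset
      neuron$ref_left <- neuron$t_ref
    }
  }
  list(neuron = neuron, spiked = spiked)
}

#' Poisson spike train
#'
#' Homogeneous Poisson process realization on `[t0, t1)`, generated by
#' exponential inter-arrival times from a counter-based noise stream:
#' the same stream state always produces the same train.
#'
#' @param rate rate in Hz (>= 0).
#' @param t0,t1 interval bounds in ms (`t1 > t0`).
#' @param stream a [noise_stream()].
#' @return Numeric vector of spike times (ms).
#' @export
poisson_spikes <- function(rate, t0, t1, stream) {
  if (rate < 0) stop("rate must be non-negative")
  if (t1 <= t0) stop("t1 must exceed t0")
  if (rate == 0) return(numeric(0))
  rate_ms <- rate / 1000
  times <- numeric(0)
  t <- t0
  # expected count plus slack; extend if the tail was underestimated
  repeat {
    u <- .stream_uniform(stream)
    t <- t - log(1 - u) / rate_ms
    if (t >= t1) break
    times <- c(times, t)
  }
  times
}

#' Regular spike train
#'
#' @param interval inter-spike interval (ms, > 0).
#' @param t0,t1 interval bounds (ms); spikes at `t0 + phase + k interval`.
#' @param phase offset of the first spike after `t0` (ms).
#' @return Numeric vector of spike times (ms).
#' @export
regular_spikes <- function(interval, t0, t1, phase = 0) {
  if (interval <= 0) stop("interval must be positive")
  out <- seq(t0 + phase, t1, by = interval)
  out[out < t1]
}

#' Time-ordered event queue
#'
#' Pending spike events sorted by delivery time; ties are delivered in
#' stable insertion order.
#'
#' @return An object of class `event_queue` (mutable environment).
#' @export
event_queue <- function() {
  q <- new.env(parent = emptyenv())
  q$time <- numeric(0)
  q$seq <- numeric(0)
  q$payload <- list()
  q$n_pushed <- 0
  class(q) <- "event_queue"
  q
}

#' @rdname event_queue
#' @param queue an `event_queue`.
#' @param time delivery time (ms).
#' @param payload arbitrary event payload (e.g. a [spike_event()]).
#' @export
queue_push <- function(queue, time, payload) {
  queue$n_pushed <- queue$n_pushed + 1
  queue$time <- c(queue$time, time)
  queue$seq <- c(queue$seq, queue$n_pushed)
  queue$payload <- c(queue$payload, list(payload))
  invisible(queue)
}

#' @rdname event_queue
#' @param t_upto pop all events with delivery time `<= t_upto`.
#' @export
queue_pop_due <- function(queue, t_upto) {
  due <- which(queue$time <= t_upto)
  if (!length(due)) return(list())
  ord <- due[order(queue$time[due], queue$seq[due])]
  out <- queue$payload[ord]
  keep <- setdiff(seq_along(queue$time), ord)
  queue$time <- queue$time[keep]
  queue$seq <- queue$seq[keep]
  queue$payload <- queue$payload[keep]
  out
}

#' Spike event record
#'
#' @param source source cell gid.
#' @param target target `(gid, synapse index)`.
#' @param t_emit emission time (ms).
#' @param delay connection delay (ms, >= 0).
#' @param weight payload weight.
#' @return A list of class `spike_event` with `t_deliver = t_emit + delay`.
#' @export
spike_event <- function(source, target, t_emit, delay = 0, weight = 0) {
  if (delay < 0) stop("connection delay must be non-negative")
  structure(list(source = source, target = target, t_emit = t_emit,
                 t_deliver = t_emit + delay, weight = weight),
            class = "spike_event")
}

#' Dispatch a postsynaptic spike to all attached mechanisms
#'
#' The postsynaptic-spike hook: when a cell spikes, every plastic mechanism
#' attached to it observes the spike time within the same timestep, without
#' explicit modelling of action-potential backpropagation. Multiple
#' co-located mechanisms (e.g. a conductance synapse plus a calcium tracker
#' on the same target) each receive the event once, as fan-out delivery
#' without per-connection labels.
#'
#' @param cell list with an element `mechanisms`: a list of mechanism objects
#'   each carrying a function `on_post(mechanism, t)` returning the updated
#'   mechanism.
#' @param t spike time (ms).
#' @return The cell with every mechanism updated.
#' @export
post_event_dispatch <- function(cell, t) {
  for (i in seq_along(cell$mechanisms)) {
    mech <- cell$mechanisms[[i]]
    if (!is.null(mech$on_post))
      cell$mechanisms[[i]] <- mech$on_post(mech, t)
  }
  cell
}

#' Write a spike raster as two-column text
#'
#' @param times,gids spike times (ms) and cell gids.
#' @param path output path.
#' @param seed,config_hash recorded in the header line.
#' @return `path`, invisibly.
#' @export
write_raster <- function(times, gids, path, seed = NA, config_hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# time_ms gid seed=%s config=%s", seed, config_hash),
             con)
  writeLines(sprintf("%.6f %d", times, as.integer(gids)), con)
  invisible(path)
}
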