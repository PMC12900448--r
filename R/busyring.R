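#' Build a busyring benchmark network
#'
#' Rings of `k` multi-compartment neurons tuned to propagate a single spike
#' indefinitely: within each ring, neuron `i` excites neuron `i + 1` with a
#' uniform delay `t_delay` and a non-zero conductance weight, so that after
#' the initial kick every neuron fires at frequency `1 / (k t_delay)`. In
#' addition, `s` zero-weight connections per cell target random endpoints:
#' they load the event-delivery machinery but have no effect on their
#' targets. The zero-weight connections can optionally carry STDP
#' mechanisms, whose traces are updated on every delivered event while the
#' delivered weight stays zero (the connection weight), leaving the raster
#' unchanged.
#'
#' Cells are `simple-branchy`: a Hodgkin-Huxley soma plus a random
#' leak-only dendritic tree of the given depth, generated per cell from a
#' per-cell counter-based stream.
#'
#' @param n_cells total number of cells (divisible by `k`).
#' @param k ring size.
#' @param s zero-weight connections per cell.
#' @param t_delay synaptic delay (ms).
#' @param w_ring ring synapse conductance (uS).
#' @param tree_depth dendritic tree depth (0 = soma only).
#' @param seed global seed.
#' @param stdp optional [stdp_params()] attached to zero-weight synapses.
#' @return An object of class `busyring`.
#' @export
busyring_build <- function(n_cells = 8, k = 4, s = 0, t_delay = 5,
                           w_ring = 0.1, tree_depth = 1, seed = 1,
                           stdp = NULL) {
  if (k < 2) stop("ring size k must be at least 2")
  if (n_cells %% k != 0) stop("n_cells must be divisible by k")
  cells <- lapply(seq_len(n_cells), function(gid)
    .busyring_cell(gid, tree_depth, seed))
  ring_of <- (seq_len(n_cells) - 1) %/% k
  nxt <- ifelse((seq_len(n_cells) %% k) == 0,
                seq_len(n_cells) - k + 1L, seq_len(n_cells) + 1L)
  conns <- data.frame(src = seq_len(n_cells), dst = nxt, w = w_ring,
                      delay = t_delay)
  if (s > 0) {
    # s random zero-weight endpoints per cell, drawn from per-cell streams
    rnd <- do.call(rbind, lapply(seq_len(n_cells), function(gid) {
      u <- .tf_uniforms_batch(
        matrix(rep(c(seed, gid, 9, 0), s), ncol = 4, byrow = TRUE),
        seq_len(s) - 1)[, 1]
      data.frame(src = gid, dst = 1L + as.integer(floor(u * n_cells)),
                 w = 0, delay = t_delay)
    }))
    conns <- rbind(conns, rnd)
  }
  stdp_syns <- NULL
  if (!is.null(stdp)) {
    zi <- which(conns$w == 0)
    stdp_syns <- lapply(zi, function(i) stdp_synapse(stdp))
    names(stdp_syns) <- as.character(zi)
  }
  structure(list(n_cells = n_cells, k = k, s = s, t_delay = t_delay,
                 w_ring = w_ring, cells = cells, conns = conns,
                 ring_of = ring_of, stdp = stdp_syns, seed = seed),
            class = "busyring")
}

# random leak-only tree on a Hodgkin-Huxley soma; geometry drawn from the
# per-cell stream so every cell differs but is reproducible
.busyring_cell <- function(gid, depth, seed) {
  segs <- data.frame(id = 1L, parent = NA_integer_, prox_radius = 10,
                     dist_radius = 10, length = 20, tag = "soma")
  tips <- 1L
  nid <- 1L
  ctr <- 0
  draw <- function() {
    ctr <<- ctr + 1
    .tf_uniforms(c(seed, gid, 8, 0), ctr - 1)
  }
  for (d in seq_len(depth)) {
    new_tips <- integer(0)
    for (tp in tips) {
      u <- draw()
      n_child <- 1L + (u[1] < 0.5)
      for (ch in seq_len(n_child)) {
        nid <- nid + 1L
        segs <- rbind(segs, data.frame(
          id = nid, parent = tp, prox_radius = 0.5 + u[2],
          dist_radius = 0.5 + u[2], length = 20 + 60 * u[1 + ch],
          tag = "dendrite"))
        new_tips <- c(new_tips, nid)
      }
    }
    tips <- new_tips
  }
  morph <- morphology(segs)
  grid <- discretize(morph, 10)
  soma_comp <- grid$seg_first[match(1L, grid$segments$id)]
  list(grid = grid, soma = soma_comp)
}

#' Run a busyring network
#'
#' Fixed-dt simulation: every cell's cable equation is stepped implicitly;
#' ring synapses are conductance-based exponential synapses on the soma
#' (reversal 0 mV, time constant `tau_syn`); one neuron per ring receives a
#' single external kick at `t_kick`. Spikes are detected as upward somatic
#' zero crossings; each spike schedules delivery on all outgoing
#' connections after their delay.
#'
#' @param net a [busyring_build()] network.
#' @param t_end simulated time (ms).
#' @param dt step (ms).
#' @param tau_syn synaptic time constant (ms).
#' @param t_kick time of the external kick (ms).
#' @param w_kick kick conductance (uS).
#' @return List with `raster` (`t`, `gid`), `n_delivered` events, and (when
#'   STDP synapses are attached) the updated synapses.
#' @export
busyring_run <- function(net, t_end = 200, dt = 0.025, tau_syn = 2,
                         t_kick = 1, w_kick = 0.2) {
  stopifnot(inherits(net, "busyring"))
  n <- net$n_cells
  states <- lapply(net$cells, function(cl)
    membrane_state(cl$grid, v0 = -65, g_leak = 0.3, e_leak = -54.4,
                   hh_comps = cl$soma))
  g_syn <- numeric(n)
  dec <- exp(-dt / tau_syn)
  # per-source outgoing connections
  out_by_src <- split(seq_len(nrow(net$conns)), net$conns$src)
  by_target_stdp <- if (!is.null(net$stdp))
    split(as.integer(names(net$stdp)), net$conns$dst[as.integer(names(net$stdp))])
  n_steps <- round(t_end / dt)
  delay_steps <- round(net$conns$delay / dt)
  ring_len <- max(delay_steps) + 1L
  ring <- rep(list(integer(0)), ring_len)  # per slot: due connection ids
  pos <- 1L
  kick_targets <- which((seq_len(n) - 1) %% net$k == 0)
  kick_step <- max(1L, round(t_kick / dt))
  vprev <- vapply(seq_len(n), function(i) states[[i]]$v[net$cells[[i]]$soma],
                  numeric(1))
  last_spike <- rep(-Inf, n)
  raster_t <- numeric(0); raster_gid <- integer(0)
  n_delivered <- 0
  stdp_syns <- net$stdp
  for (s in seq_len(n_steps)) {
    t <- s * dt
    # deliveries due this step
    due <- ring[[pos]]
    if (length(due)) {
      n_delivered <- n_delivered + length(due)
      w_due <- net$conns$w[due]
      nz <- which(w_due != 0)
      for (k in nz)
        g_syn[net$conns$dst[due[k]]] <- g_syn[net$conns$dst[due[k]]] + w_due[k]
      if (!is.null(stdp_syns)) {
        for (ci in due) {
          id <- as.character(ci)
          if (!is.null(stdp_syns[[id]]))
            stdp_syns[[id]] <- stdp_on_spike(stdp_syns[[id]], t, "pre")
        }
      }
    }
    ring[[pos]] <- integer(0)
    if (s == kick_step)
      g_syn[kick_targets] <- g_syn[kick_targets] + w_kick
    spiked <- integer(0)
    for (i in seq_len(n)) {
      soma <- net$cells[[i]]$soma
      # conductance-based synaptic current onto the soma (reversal 0 mV)
      ist <- if (g_syn[i] > 0)
        list(list(comp = soma, current = g_syn[i] * (0 - states[[i]]$v[soma])))
      else list()
      states[[i]] <- step_voltage(states[[i]], net$cells[[i]]$grid, ist, dt)
      v <- states[[i]]$v[soma]
      if (vprev[i] < 0 && v >= 0 && t - last_spike[i] > 2) {
        spiked <- c(spiked, i)
        last_spike[i] <- t
      }
      vprev[i] <- v
    }
    g_syn <- g_syn * dec
    for (src in spiked) {
      raster_t <- c(raster_t, t)
      raster_gid <- c(raster_gid, src)
      outs <- out_by_src[[as.character(src)]]
      slots <- (pos - 1L + delay_steps[outs]) %% ring_len + 1L
      for (sl in unique(slots))
        ring[[sl]] <- c(ring[[sl]], outs[slots == sl])
      # postsynaptic spike fan-out to STDP mechanisms targeting this cell
      if (!is.null(stdp_syns) && !is.null(by_target_stdp[[as.character(src)]])) {
        for (id in by_target_stdp[[as.character(src)]]) {
          key <- as.character(id)
          stdp_syns[[key]] <- stdp_on_spike(stdp_syns[[key]], t, "post")
        }
      }
    }
    pos <- pos %% ring_len + 1L
  }
  list(raster = list(t = raster_t, gid = raster_gid),
       n_delivered = n_delivered, stdp = stdp_syns)
}
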