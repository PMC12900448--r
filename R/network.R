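#' Recipe for a recurrent plastic network
#'
#' Describes a sparse recurrent network of `n` neurons (`n_exc` excitatory)
#' with Bernoulli(`p_conn`) connectivity and no self-connections.
#' Excitatory-to-excitatory synapses are plastic and follow the
#' tagging-and-capture model (in vivo calcium correction); all other
#' connections are static. Neurons are LIF with exponential synaptic
#' currents and a white-noise background current.
#'
#' Reduced networks keep the connection probability and the
#' assembly-to-population ratio of the full-size (2000-neuron) condition.
#' Per-synapse couplings are kept at their full-size values
#' (`weight_gain = 1` by default): upscaling weights by `n_full / n` to
#' preserve the mean input brings single excitatory potentials close to
#' threshold and tips the reduced network into seizure-like activity, so
#' the reduced network instead operates at the native coupling with a
#' correspondingly sparser recurrent drive. Pass `n_full` to restore the
#' mean-input-preserving gain for exploration.
#'
#' The static coupling strengths (`w_ei`, `w_ie`, `w_ii`, in mV, the latter
#' two applied with negative sign) are configuration constants chosen to
#' give stable, sparse background activity (about 1-3 Hz) while confining
#' stimulus-driven firing to the stimulated assembly; the defaults are
#' expressed in multiples of the baseline coupling `h0 = 4.20075` mV
#' (`w_ei = 2 h0`, `w_ie = 6 h0`, `w_ii = 2 h0`).
#'
#' The default network neuron uses an 8-ms absolute refractory period (a
#' strong after-hyperpolarization limiting sustained firing to about
#' 110 Hz). This rate cap is what makes assembly learning work in the
#' reduced network: it keeps the stimulated assembly's response homogeneous
#' (without it, feedback inhibition plus recurrent potentiation produce a
#' winner-take-all response) and pins assembly firing just below the rate
#' at which presynaptic calcium alone would cross the potentiation
#' threshold, so potentiation requires coincident postsynaptic activity
#' and stays specific to synapses within the assembly while
#' assembly-to-outside synapses depress.
#'
#' @param n,n_exc network and excitatory-population sizes.
#' @param p_conn connection probability in `[0, 1]`.
#' @param seed seed for connectivity and all noise streams.
#' @param dt integration step (ms).
#' @param neuron [stc_neuron_defaults()].
#' @param plasticity [stc_params()] with `in_vivo = TRUE`.
#' @param w_ei,w_ie,w_ii static coupling strengths (mV).
#' @param n_full reference full size for the weight-gain scaling rule.
#' @param variant `NULL` for (approximate) point neurons, or a
#'   [morpho_cell_spec()] for morphological cells (its `c_morpho` factor
#'   multiplies recurrent excitatory couplings; intracellular signalling
#'   then runs on the cell's compartment grid).
#' @param plasticity_noise logical.
#' @param normalize_inhibition logical; scale every neuron's incoming
#'   inhibitory weights so the summed inhibitory weight equals its
#'   expectation (`p_conn (n - n_exc) w`). In a small network the Bernoulli
#'   spread of the inhibitory in-degree (about 30% here) otherwise imposes
#'   large quenched rate differences between neurons; this homeostatic
#'   scaling keeps the stimulated-assembly response homogeneous.
#' @return An object of class `network_recipe`.
#' @export
network_recipe <- function(n = 500, n_exc = 400, p_conn = 0.1, seed = 1,
                           dt = 0.5, neuron = stc_neuron_defaults(t_ref = 8),
                           plasticity = stc_params(in_vivo = TRUE),
                           w_ei = 2 * plasticity$h0,
                           w_ie = 6 * plasticity$h0,
                           w_ii = 2 * plasticity$h0,
                           n_full = NULL, variant = NULL,
                           plasticity_noise = TRUE,
                           normalize_inhibition = TRUE) {
  if (p_conn < 0 || p_conn > 1) stop("p_conn must be in [0, 1]")
  if (n_exc > n) stop("n_exc cannot exceed n")
  structure(list(n = n, n_exc = n_exc, p_conn = p_conn, seed = seed,
                 dt = dt, neuron = neuron, plasticity = plasticity,
                 w_ei = w_ei, w_ie = w_ie, w_ii = w_ii,
                 weight_gain = if (is.null(n_full)) 1 else n_full / n,
                 variant = variant,
                 plasticity_noise = plasticity_noise,
                 normalize_inhibition = normalize_inhibition),
            class = "network_recipe")
}

#' Build a network from a recipe
#'
#' Draws the Bernoulli connectivity deterministically from the recipe seed
#' (counter-based streams: the same recipe always yields the same network),
#' assembles the compressed adjacency used by the simulation engine, and
#' initializes all state (potentials at rest, plastic weights at `h0`,
#' late phase and calcium at zero, empty delivery buffers).
#'
#' @param recipe a [network_recipe()].
#' @return An object of class `stc_network`.
#' @export
build_network <- function(recipe) {
  stopifnot(inherits(recipe, "network_recipe"))
  n <- recipe$n
  n_exc <- recipe$n_exc
  # adjacency: one uniform per ordered pair, keyed by source row
  src <- integer(0); dst <- integer(0)
  if (recipe$p_conn > 0) {
    for (i in seq_len(n) - 1L) {
      u <- .tf_uniforms_batch(
        matrix(rep(c(recipe$seed, i, 4, 0), n), ncol = 4, byrow = TRUE),
        seq_len(n) - 1)[, 1]
      hit <- which(u < recipe$p_conn) - 1L
      hit <- hit[hit != i]
      src <- c(src, rep(i, length(hit)))
      dst <- c(dst, hit)
    }
  }
  is_exc_src <- src < n_exc
  is_exc_dst <- dst < n_exc
  plastic <- is_exc_src & is_exc_dst
  # plastic synapse arrays
  p_src <- src[plastic]; p_dst <- dst[plastic]
  n_plast <- length(p_src)
  # static synapses with signed weights
  s_src <- src[!plastic]; s_dst <- dst[!plastic]
  s_w <- ifelse(is_exc_src[!plastic], recipe$w_ei, ifelse(
    is_exc_dst[!plastic], -recipe$w_ie, -recipe$w_ii))
  if (isTRUE(recipe$normalize_inhibition)) {
    # homeostatic scaling of inhibitory inputs: every neuron receives the
    # same summed inhibitory weight, removing the quenched in-degree
    # disorder that otherwise dominates the reduced network's response
    inh_syn <- which(s_w < 0)
    if (length(inh_syn)) {
      k_in <- tabulate(s_dst[inh_syn] + 1L, nbins = n)
      target_total <- recipe$p_conn * (n - n_exc)
      sc <- ifelse(k_in > 0, target_total / k_in, 1)
      s_w[inh_syn] <- s_w[inh_syn] * sc[s_dst[inh_syn] + 1L]
    }
  }
  csr <- function(srcv, n) {
    ord <- order(srcv)
    ptr <- c(0L, cumsum(tabulate(srcv + 1L, nbins = n)))
    list(ord = ord, ptr = as.integer(ptr))
  }
  cs <- csr(s_src, n)
  cp <- csr(p_src, n)
  ct <- csr(p_dst, n)
  pl <- recipe$plasticity
  delay_steps <- max(1L, as.integer(round(recipe$neuron$delay / recipe$dt)))
  delay_inh <- if (is.null(recipe$neuron$delay_inh)) recipe$neuron$delay else
    recipe$neuron$delay_inh
  delay_steps_inh <- max(1L, as.integer(round(delay_inh / recipe$dt)))
  tc_steps <- max(1L, as.integer(round(pl$tc_delay / recipe$dt)))
  c_morpho <- if (is.null(recipe$variant)) 1.0 else recipe$variant$c_morpho
  par <- list(dt = recipe$dt,
              v_rest = recipe$neuron$v_rest, v_reset = recipe$neuron$v_reset,
              v_thresh = recipe$neuron$v_thresh, tau_m = recipe$neuron$tau_m,
              r_m = recipe$neuron$r_m, t_ref = recipe$neuron$t_ref,
              tau_syn = recipe$neuron$tau_syn, delay_steps = delay_steps,
              delay_steps_inh = delay_steps_inh, n_exc = n_exc,
              h0 = pl$h0, tau_h = pl$tau_h, tau_c = pl$tau_c,
              gamma_p = pl$gamma_p, gamma_d = pl$gamma_d,
              theta_p = pl$theta_p, theta_d = pl$theta_d,
              c_pre = pl$c_pre, c_post = pl$c_post, sigma_pl = pl$sigma_pl,
              tau_p = pl$tau_p, p_max = pl$p_max, theta_pro = pl$theta_pro,
              theta_tag = pl$theta_tag, f_int = pl$f_int, tau_z = pl$tau_z,
              tc_delay_steps = tc_steps, weight_gain = recipe$weight_gain,
              c_morpho = c_morpho, bg_i0 = recipe$neuron$bg_i0,
              bg_sigma = recipe$neuron$bg_sigma,
              plasticity_noise = recipe$plasticity_noise,
              plasticity_on = TRUE, seed = recipe$seed)
  net <- list(n = n,
              s_ptr = cs$ptr, s_dst = as.integer(s_dst[cs$ord]),
              s_w = s_w[cs$ord],
              p_ptr = cp$ptr, p_idx = as.integer(cp$ord - 1L),
              p_dst = as.integer(p_dst),
              t_ptr = ct$ptr, t_idx = as.integer(ct$ord - 1L),
              par = par)
  state <- list(v = rep(recipe$neuron$v_rest, n), ref_left = numeric(n),
                i_syn = numeric(n), h = rep(pl$h0, n_plast),
                z = numeric(n_plast), c = numeric(n_plast), p = numeric(n),
                ring = matrix(0, n, max(delay_steps, delay_steps_inh) + 1L),
                ca_ring = rep(list(integer(0)), tc_steps + 1L),
                ring_pos = 0L, ca_pos = 0L, step = 0)
  structure(list(recipe = recipe, net = net, state = state,
                 p_src = p_src, p_dst = p_dst, t_now = 0),
            class = "stc_network")
}

#' @export
print.stc_network <- function(x, ...) {
  cat(sprintf(
    "<stc_network: %d neurons (%d exc), %d plastic + %d static synapses, t = %.4g s>\n",
    x$net$n, x$recipe$n_exc, length(x$p_src), length(x$net$s_dst),
    x$t_now / 1000))
  invisible(x)
}

#' Run a schedule of simulation phases
#'
#' Full phases integrate membrane, synaptic, calcium, and plasticity
#' dynamics at the fine step; fast-forward phases advance only the slow
#' variables (early-phase relaxation, late phase, protein pools) at a coarse
#' step. All state, including delivery buffers and the noise-stream step
#' counter, carries across phase boundaries exactly, so splitting a full
#' phase into consecutive phases leaves the trajectory bit-identical.
#'
#' @param network an [build_network()] result.
#' @param phases list of phases, each a list with `mode` (`"full"` or
#'   `"ff"`), `t_end` (ms, must be non-decreasing across phases), and for
#'   full phases optional `stim` (data frame `t0, t1, rate, weight`) plus
#'   `stim_targets` (list of gid vectors, one per stim row) and `record`
#'   (logical, default `TRUE`).
#' @param dt_ff coarse step of fast-forward phases (ms).
#' @return The network with updated state and accumulated raster
#'   (`raster$t`, `raster$gid`, 1-based gids).
#' @export
run_phases <- function(network, phases, dt_ff = 1000) {
  stopifnot(inherits(network, "stc_network"))
  raster_t <- network$raster$t
  raster_gid <- network$raster$gid
  for (ph in phases) {
    if (ph$t_end < network$t_now) stop("phases must be contiguous in time")
    if (ph$t_end == network$t_now) next
    if (ph$mode == "full") {
      stim <- if (is.null(ph$stim)) {
        matrix(0, 0, 4)
      } else {
        as.matrix(ph$stim[, c("t0", "t1", "rate", "weight")])
      }
      tg <- if (is.null(ph$stim_targets)) list() else
        lapply(ph$stim_targets, function(g) as.integer(g - 1L))
      res <- .stc_network_cpp(network$net, network$state,
                              list(t_start = network$t_now,
                                   t_end = ph$t_end, stim = stim,
                                   stim_targets = tg,
                                   record_spikes = !isFALSE(ph$record)))
      network$state <- res$state
      raster_t <- c(raster_t, res$spike_t)
      raster_gid <- c(raster_gid, res$spike_gid + 1L)
    } else if (ph$mode == "ff") {
      network$state <- .network_fast_forward(network, ph$t_end, dt_ff)
    } else stop("unknown phase mode: ", ph$mode)
    network$t_now <- ph$t_end
  }
  network$raster <- list(t = raster_t, gid = raster_gid)
  network
}

# fast-forward of the network's slow variables; spiking, membrane and
# calcium are frozen (calcium is cleared: it decays within milliseconds)
.network_fast_forward <- function(network, t_end, dt_ff) {
  st <- network$state
  pl <- network$recipe$plasticity
  t_span <- t_end - network$t_now
  n_steps <- ceiling(t_span / dt_ff)
  dec_h <- exp(-0.1 * dt_ff / pl$tau_h)
  dec_p <- exp(-dt_ff / pl$tau_p)
  post <- network$p_dst + 1L
  n <- network$net$n
  for (k in seq_len(n_steps)) {
    dev <- abs(st$h - pl$h0)
    sumdev <- numeric(n)
    if (length(dev)) {
      agg <- rowsum(dev, post)
      sumdev[as.integer(rownames(agg))] <- agg[, 1]
    }
    target <- ifelse(sumdev >= pl$theta_pro, pl$p_max, 0)
    p_syn <- st$p[post]
    tag_up <- as.numeric((st$h - pl$h0) >= pl$theta_tag)
    tag_dn <- as.numeric((pl$h0 - st$h) >= pl$theta_tag)
    st$z <- st$z + dt_ff / pl$tau_z *
      (p_syn * pl$f_int * (1 - st$z) * tag_up -
         p_syn * pl$f_int * (st$z + 0.5) * tag_dn)
    st$p <- target + (st$p - target) * dec_p
    st$h <- pl$h0 + (st$h - pl$h0) * dec_h
  }
  st$c[] <- 0
  st$v[] <- network$recipe$neuron$v_rest
  st$i_syn[] <- 0
  st$ref_left[] <- 0
  st$ring[] <- 0
  st$ca_ring <- rep(list(integer(0)), length(st$ca_ring))
  st$step <- st$step + round(t_span / network$recipe$dt)
  st
}

#' Pattern completion coefficient
#'
#' `Q = (rate_ans - rate_ctrl) / rate_as` from mean firing rates in a
#' window centred at the recall readout time: `as` are assembly neurons
#' stimulated during both learning and recall, `ans` assembly neurons not
#' stimulated during recall, and `ctrl` excitatory neurons outside the
#' assembly. `Q > 0` indicates successful pattern completion.
#'
#' @param raster list with `t` (ms) and `gid` (1-based).
#' @param subpops list with integer gid vectors `as`, `ans`, `ctrl`.
#' @param t_center window centre (ms).
#' @param window window length (ms), default 500.
#' @return Scalar `Q`.
#' @export
compute_Q <- function(raster, subpops, t_center, window = 500) {
  t0 <- t_center - window / 2
  t1 <- t_center + window / 2
  rate <- function(gids) {
    if (!length(gids)) stop("empty subpopulation")
    sel <- raster$t >= t0 & raster$t < t1 & raster$gid %in% gids
    sum(sel) / length(gids) / (window / 1000)
  }
  nu_as <- rate(subpops$as)
  if (nu_as == 0)
    stop("undefined Q: the recall-stimulated subpopulation is silent")
  (rate(subpops$ans) - rate(subpops$ctrl)) / nu_as
}

#' Renormalized protein-synthesis threshold
#'
#' When the synthesis trigger compares a somatic concentration instead of a
#' total amount, the threshold must be divided by the total cell volume:
#' `theta_pro* = theta_pro / sum_i V_i`.
#'
#' @param theta_pro amount-based threshold.
#' @param grid the cell's [discretize()] grid.
#' @return `theta_pro` divided by the summed compartment volumes (um^3).
#' @export
renormalized_threshold <- function(theta_pro, grid) {
  vtot <- sum(grid$volume)
  if (vtot <= 0) stop("total cell volume must be positive")
  theta_pro / vtot
}

#' Intracellular signalling state of a morphological cell
#'
#' Creates the two diffusing fields used for tag-to-soma signalling and
#' protein distribution on a cell grid: the synthesis-triggering signal
#' (SPS), injected at synapse locations so that its total amount tracks the
#' summed early-phase weight change, and the protein (PRP) field, produced
#' in the designated synthesis compartment while the somatic SPS
#' concentration exceeds the volume-renormalized threshold.
#'
#' @param spec a [morpho_cell_spec()].
#' @param params [stc_params()].
#' @param d_sps SPS diffusivity (m^2/s).
#' @param d_p PRP diffusivity (m^2/s).
#' @return An object of class `sps_cell`.
#' @export
sps_cell <- function(spec, params = stc_params(in_vivo = TRUE),
                     d_sps = 1e-11, d_p = 1e-11) {
  grid <- spec$grid
  structure(list(
    grid = grid, params = params,
    sps = species_field(grid, "sps", conc = 0, D = d_sps),
    prp = species_field(grid, "prp", conc = 0, D = d_p,
                        decay_tau = params$tau_p),
    soma_center = spec$soma_center, synth_comp = spec$soma_center,
    basal_tip = spec$basal_tip, apical_tip = spec$apical_tip,
    theta_pro_star = renormalized_threshold(params$theta_pro, grid),
    synthesizing = FALSE),
    class = "sps_cell")
}

#' One step of the tag-signalling / protein-distribution coupling
#'
#' Each synapse deposits the change of its early-phase deviation
#' `|h - h0|` as SPS at its dendritic compartment (so the total SPS amount
#' equals `sum |h - h0|` in the instantaneous-mixing limit); SPS diffuses;
#' the SPS concentration at the soma centre is compared against the
#' volume-renormalized threshold; while it is exceeded, PRP is produced in
#' the synthesis compartment (at the rate that reduces to the scalar pool
#' dynamics under instantaneous mixing) and diffuses with its own
#' diffusivity while decaying with `tau_p`. Each synapse then reads its
#' local PRP concentration. For a single-compartment cell the update
#' reduces exactly to [prp_step()] on the scalar pool.
#'
#' @param cell an [sps_cell()].
#' @param syn_comp integer vector: compartment of each synapse.
#' @param dev current `|h - h0|` per synapse (mV).
#' @param dev_prev value of `dev` at the previous step.
#' @param dt step (ms).
#' @return List `(cell, p_local)` with the per-synapse PRP concentration.
#' @export
sps_prp_coupling <- function(cell, syn_comp, dev, dev_prev, dt) {
  stopifnot(inherits(cell, "sps_cell"))
  if (is.null(cell$synth_comp) || is.na(cell$synth_comp))
    stop("cell has no synthesis compartment")
  if (any(syn_comp < 1 | syn_comp > cell$grid$n))
    stop("synapse compartment off the grid")
  grid <- cell$grid
  # SPS bookkeeping: deposit the deviation increment at the synapse site
  cell$sps$source[] <- 0
  dinc <- (dev - dev_prev) / dt / grid$volume[syn_comp]
  for (i in seq_along(syn_comp))
    cell$sps$source[syn_comp[i]] <- cell$sps$source[syn_comp[i]] + dinc[i]
  cell$sps <- step_diffusion(cell$sps, grid, dt)
  cell$sps$conc <- pmax(cell$sps$conc, 0)
  cell$synthesizing <- cell$sps$conc[cell$soma_center] >= cell$theta_pro_star
  pr <- cell$params
  if (grid$n == 1L) {
    # instantaneous mixing: exact scalar pool update
    target <- if (cell$synthesizing) pr$p_max else 0
    cell$prp$conc <- target + (cell$prp$conc - target) * exp(-dt / pr$tau_p)
  } else {
    cell$prp$source[] <- 0
    if (cell$synthesizing)
      cell$prp$source[cell$synth_comp] <-
        pr$p_max * sum(grid$volume) / (pr$tau_p * grid$volume[cell$synth_comp])
    cell$prp <- step_diffusion(cell$prp, grid, dt)
  }
  list(cell = cell, p_local = cell$prp$conc[syn_comp])
}

#' Memory recall experiment
#'
#' Builds a recurrent network, stimulates a neuron assembly with a learning
#' protocol, optionally consolidates (fast-forward), applies recall
#' stimulation to half the assembly, and measures the pattern completion
#' coefficient in a 0.5-s window at recall readout.
#'
#' Schedule (compressed relative to real-time experiments; window length
#' kept at 0.5 s): background settling, three 0.5-s learning pulses, then
#' recall with a 0.1-s pulse to half the assembly `recall_after` ms after
#' the end of learning; `Q` is read out 100 ms after recall onset. For
#' `recall_after` longer than `ff_threshold` the gap is fast-forwarded.
#'
#' The stimulation strength is expressed as a Poisson arrival rate of
#' unitary inputs of weight `h0`: the default 3600 arrivals/s drives
#' assembly neurons to several tens of Hz against the feedback inhibition,
#' the operating point at which presynaptic calcium alone mostly stays
#' below the potentiation threshold while correlated pre- and postsynaptic
#' firing crosses it, so that potentiation is biased towards synapses
#' within the stimulated assembly.
#'
#' @param recipe a [network_recipe()].
#' @param assembly_size number of neurons receiving the learning stimulus.
#' @param recall_after gap between learning end and recall onset (ms);
#'   10 s for the short paradigm, 8 h for the consolidation paradigm.
#' @param learn logical; `FALSE` omits the learning stimulus (control).
#' @param stim_rate,stim_weight Poisson stimulation rate (Hz) and weight
#'   (mV, default `h0`) of learning/recall pulses.
#' @param learn_pulse,learn_gap pulse length and inter-pulse gap (ms).
#' @param t_settle settling time before learning (ms).
#' @param ff_threshold gaps longer than this are fast-forwarded (ms).
#' @return List with `Q`, the `raster`, the subpopulations, rates, and the
#'   final network.
#' @export
recall_experiment <- function(recipe, assembly_size = 60,
                              recall_after = 10e3, learn = TRUE,
                              stim_rate = 3600, stim_weight = NULL,
                              learn_pulse = 500, learn_gap = 200,
                              t_settle = 500, ff_threshold = 30e3) {
  if (assembly_size > recipe$n_exc)
    stop("assembly size cannot exceed the excitatory population")
  if (is.null(stim_weight)) stim_weight <- recipe$plasticity$h0
  network <- build_network(recipe)
  assembly <- seq_len(assembly_size)
  recall_set <- seq_len(ceiling(assembly_size / 2))
  subpops <- list(as = recall_set,
                  ans = setdiff(assembly, recall_set),
                  ctrl = setdiff(seq_len(recipe$n_exc), assembly))
  t_learn <- t_settle + (0:2) * (learn_pulse + learn_gap)
  learn_end <- t_learn[3] + learn_pulse
  stim <- data.frame(t0 = t_learn, t1 = t_learn + learn_pulse,
                     rate = stim_rate, weight = stim_weight)
  targets <- rep(list(assembly), 3)
  if (!learn) {
    stim <- stim[0, ]
    targets <- list()
  }
  recall_on <- learn_end + recall_after
  t_readout <- recall_on + 200
  phases <- list()
  phases[[1]] <- list(mode = "full", t_end = learn_end + 200, stim = stim,
                      stim_targets = targets)
  gap_end <- recall_on - 500
  if (recall_after > ff_threshold) {
    phases[[2]] <- list(mode = "ff", t_end = gap_end)
    phases[[3]] <- list(mode = "full", t_end = recall_on)
  } else {
    phases[[2]] <- list(mode = "full", t_end = recall_on)
  }
  phases[[length(phases) + 1]] <-
    list(mode = "full", t_end = t_readout + 600,
         stim = data.frame(t0 = recall_on, t1 = recall_on + 100,
                           rate = stim_rate, weight = stim_weight),
         stim_targets = list(recall_set))
  network <- run_phases(network, Filter(Negate(is.null), phases))
  Q <- compute_Q(network$raster, subpops, t_readout)
  rate_of <- function(g) {
    sel <- network$raster$t >= t_readout - 250 &
      network$raster$t < t_readout + 250 & network$raster$gid %in% g
    sum(sel) / length(g) / 0.5
  }
  list(Q = Q, raster = network$raster, subpops = subpops,
       rates = c(as = rate_of(subpops$as), ans = rate_of(subpops$ans),
                 ctrl = rate_of(subpops$ctrl)),
       t_readout = t_readout, network = network)
}
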