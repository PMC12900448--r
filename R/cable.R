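#' Membrane state on a compartment grid
#'
#' Carries the per-compartment membrane potential and the membrane mechanisms
#' for implicit cable-equation stepping. The leak mechanism is always
#' present; Hodgkin-Huxley sodium/potassium channels (classical squid-axon
#' rate functions) can be enabled on a subset of compartments.
#'
#' Units: potential mV, time ms, specific capacitance uF/cm^2, specific
#' conductance mS/cm^2, axial resistivity Ohm cm. Internally capacitances are
#' nF, currents nA, conductances uS.
#'
#' @param grid a [discretize()] grid.
#' @param v0 initial potential (mV), recycled.
#' @param c_m specific membrane capacitance (uF/cm^2).
#' @param r_l axial resistivity (Ohm cm).
#' @param g_leak leak conductance (mS/cm^2).
#' @param e_leak leak reversal potential (mV).
#' @param hh_comps integer indices of compartments carrying Hodgkin-Huxley
#'   channels (empty for a passive cell).
#' @param hh list of Hodgkin-Huxley densities/reversals, see
#'   [hh_parameters()].
#' @return An object of class `membrane_state`.
#' @export
membrane_state <- function(grid, v0 = -65, c_m = 1.0, r_l = 100,
                           g_leak = 0.3, e_leak = -65,
                           hh_comps = integer(0), hh = hh_parameters()) {
  stopifnot(inherits(grid, "compartment_grid"))
  n <- grid$n
  v <- rep_len(v0, n)
  area_cm2 <- grid$area_lateral * 1e-8
  cap_nF <- c_m * area_cm2 * 1e3          # uF -> nF
  gl_uS <- g_leak * area_cm2 * 1e3        # mS -> uS
  # axial conductance in uS: series coupling with q = 1/r_l, lengths um ->
  # cm (1e-4), areas um^2 -> cm^2 (1e-8); resulting S -> uS (1e6)
  g_ax <- .series_coupling(grid, 1 / r_l) * 1e-8 / 1e-4 * 1e6
  st <- list(v = v, cap = cap_nF, g_leak = gl_uS, e_leak = e_leak,
             g_axial = g_ax, hh_comps = as.integer(hh_comps), hh = hh)
  if (length(hh_comps)) {
    vr <- v[hh_comps]
    st$m <- .hh_inf("m", vr); st$h <- .hh_inf("h", vr); st$n_gate <- .hh_inf("n", vr)
    st$g_na <- hh$g_na * area_cm2[hh_comps] * 1e3
    st$g_k <- hh$g_k * area_cm2[hh_comps] * 1e3
  }
  class(st) <- "membrane_state"
  st
}

#' Hodgkin-Huxley channel parameters
#'
#' The classical squid-axon parameter set: sodium 120 mS/cm^2 (reversal
#' +50 mV), delayed-rectifier potassium 36 mS/cm^2 (-77 mV), with the
#' standard rate functions shifted to a resting potential near -65 mV.
#'
#' @param g_na,g_k channel densities (mS/cm^2).
#' @param e_na,e_k reversal potentials (mV).
#' @return List of parameters.
#' @export
hh_parameters <- function(g_na = 120, g_k = 36, e_na = 50, e_k = -77) {
  list(g_na = g_na, g_k = g_k, e_na = e_na, e_k = e_k)
}

# classical rate functions (1/ms), v in mV; x/(1-exp(-x)) guarded at x = 0
.hh_rates <- function(gate, v) {
  linexp <- function(x) ifelse(abs(x) < 1e-7, 1 + x / 2, x / (1 - exp(-x)))
  switch(gate,
    m = list(a = linexp((v + 40) / 10),
             b = 4 * exp(-(v + 65) / 18)),
    h = list(a = 0.07 * exp(-(v + 65) / 20),
             b = 1 / (1 + exp(-(v + 35) / 10))),
    n = list(a = 0.1 * linexp((v + 55) / 10),
             b = 0.125 * exp(-(v + 65) / 80)))
}

.hh_inf <- function(gate, v) {
  r <- .hh_rates(gate, v)
  r$a / (r$a + r$b)
}

#' One implicit step of the cable equation
#'
#' Backward-Euler update of the membrane potential on the whole compartment
#' tree (unconditionally stable; Hines-ordered elimination). Gating variables
#' are advanced first by exponential integration at the current potential;
#' channel conductances then enter the implicit voltage solve.
#'
#' @param state a [membrane_state()].
#' @param grid the matching [discretize()] grid.
#' @param stimuli optional list of point-current stimuli, each
#'   `list(comp = index, current = nA)`, applied for this step.
#' @param dt step size (ms, > 0).
#' @return Updated `membrane_state`.
#' @export
step_voltage <- function(state, grid, stimuli = list(), dt) {
  stopifnot(inherits(state, "membrane_state"))
  if (dt <= 0) stop("dt must be positive")
  n <- grid$n
  g_mem <- state$g_leak
  ge_mem <- state$g_leak * state$e_leak
  if (length(state$hh_comps)) {
    ix <- state$hh_comps
    vr <- state$v[ix]
    for (gate in c("m", "h", "n")) {
      r <- .hh_rates(gate, vr)
      tau <- 1 / (r$a + r$b)
      inf <- r$a * tau
      slot <- if (gate == "n") "n_gate" else gate
      state[[slot]] <- inf + (state[[slot]] - inf) * exp(-dt / tau)
    }
    gna <- state$g_na * state$m^3 * state$h
    gk <- state$g_k * state$n_gate^4
    g_mem[ix] <- g_mem[ix] + gna + gk
    ge_mem[ix] <- ge_mem[ix] + gna * state$hh$e_na + gk * state$hh$e_k
  }
  istim <- numeric(n)
  for (st in stimuli) istim[st$comp] <- istim[st$comp] + st$current
  g_ax <- state$g_axial
  diag <- state$cap / dt + g_mem
  has_parent <- grid$parent > 0L
  ii <- which(has_parent)
  pp <- grid$parent[ii]
  add <- numeric(n)
  for (k in seq_along(ii)) {           # accumulate axial terms on both rows
    add[ii[k]] <- add[ii[k]] + g_ax[ii[k]]
    add[pp[k]] <- add[pp[k]] + g_ax[ii[k]]
  }
  diag <- diag + add
  rhs <- state$cap / dt * state$v + ge_mem + istim
  vnew <- .hines_solve(grid$parent - 1L, diag, g_ax, rhs)
  if (any(!is.finite(vnew))) stop("cable solve produced non-finite potentials")
  state$v <- vnew
  state
}

#' Diffusing particle species on a compartment grid
#'
#' A named concentration field with a diffusivity, an optional linear decay
#' time constant, and a per-compartment source term. Species carry no charge
#' and are fully decoupled from the membrane potential; boundaries are sealed
#' (zero flux) at all terminals.
#'
#' @param grid a [discretize()] grid.
#' @param name species name.
#' @param conc initial concentration (umol/l), recycled over compartments.
#' @param D diffusivity in m^2/s (converted internally to um^2/ms).
#' @param decay_tau linear decay time constant (ms), `Inf` for none.
#' @param source per-compartment source term (umol/l per ms), recycled.
#' @return An object of class `species_field`.
#' @export
species_field <- function(grid, name = "X", conc = 0, D = 0,
                          decay_tau = Inf, source = 0) {
  stopifnot(inherits(grid, "compartment_grid"))
  if (D < 0) stop("diffusivity must be non-negative")
  structure(list(name = name,
                 conc = rep_len(conc, grid$n),
                 D = D * 1e9,            # m^2/s -> um^2/ms
                 decay_tau = decay_tau,
                 source = rep_len(source, grid$n)),
            class = "species_field")
}

#' One implicit step of particle diffusion
#'
#' Backward-Euler update of `dX/dt = d/dx (D dX/dx) - X/tau + phi` on the
#' compartment tree, in conservation (finite-volume) form: with zero sources
#' and no decay the total amount `sum_i c_i V_i` is conserved to rounding.
#'
#' @param field a [species_field()].
#' @param grid the matching [discretize()] grid.
#' @param dt step size (ms, > 0).
#' @return Updated `species_field`.
#' @export
step_diffusion <- function(field, grid, dt) {
  stopifnot(inherits(field, "species_field"))
  if (dt <= 0) stop("dt must be positive")
  if (length(field$conc) != grid$n) stop("field/grid size mismatch")
  V <- grid$volume
  gd <- .series_coupling(grid, field$D)      # um^3/ms
  diag <- V / dt
  if (is.finite(field$decay_tau)) diag <- diag + V / field$decay_tau
  has_parent <- grid$parent > 0L
  ii <- which(has_parent)
  pp <- grid$parent[ii]
  add <- numeric(grid$n)
  for (k in seq_along(ii)) {
    add[ii[k]] <- add[ii[k]] + gd[ii[k]]
    add[pp[k]] <- add[pp[k]] + gd[ii[k]]
  }
  diag <- diag + add
  rhs <- V / dt * field$conc + V * field$source
  cn <- .hines_solve(grid$parent - 1L, diag, gd, rhs)
  if (any(!is.finite(cn))) stop("diffusion solve produced non-finite values")
  field$conc <- cn
  field
}
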