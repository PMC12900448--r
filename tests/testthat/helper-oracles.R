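# independent oracles used across the suite

# plain explicit-Euler diffusion on an unbranched cable (conservation form),
# used to cross-check the implicit tree solver
explicit_diffusion_oracle <- function(conc, volume, g_couple, dt, n_steps,
                                      decay_tau = Inf) {
  n <- length(conc)
  for (s in seq_len(n_steps)) {
    flux <- g_couple * (conc[-n] - conc[-1])   # between i and i+1
    dcdt <- numeric(n)
    dcdt[-n] <- dcdt[-n] - flux / volume[-n]
    dcdt[-1] <- dcdt[-1] + flux / volume[-1]
    if (is.finite(decay_tau)) dcdt <- dcdt - conc / decay_tau
    conc <- conc + dt * dcdt
  }
  conc
}

# fine-step explicit integration of the calcium-gated bistable weight drift
gb_drift_oracle <- function(w0, hp, hd, t_span, dt, params) {
  w <- w0
  n <- round(t_span / dt)
  for (s in seq_len(n)) {
    drift <- -w * (1 - w) * (params$w_star - w) +
      params$gamma_p * (1 - w) * hp - params$gamma_d * w * hd
    w <- w + drift * dt / params$tau_w
  }
  w
}

# fine-step explicit integration of the early-phase weight drift
stc_drift_oracle <- function(h0_init, hp, hd, t_span, dt, params) {
  h <- h0_init
  n <- round(t_span / dt)
  for (s in seq_len(n)) {
    drift <- 0.1 * (params$h0 - h) + params$gamma_p * (10 - h) * hp -
      params$gamma_d * h * hd
    h <- h + drift * dt / params$tau_h
  }
  h
}

# chi-square uniformity statistic against equal bins
chisq_uniform_p <- function(u, bins = 100) {
  counts <- tabulate(pmin(bins, floor(u * bins) + 1L), nbins = bins)
  expected <- length(u) / bins
  stat <- sum((counts - expected)^2 / expected)
  stats::pchisq(stat, df = bins - 1, lower.tail = FALSE)
}
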