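#' Pair-based STDP synapse
#'
#' Eligibility-trace formulation of spike-timing-dependent plasticity: each
#' presynaptic spike increments a presynaptic trace `a_pre` (decaying with
#' `tau_pre`) and changes the weight by the current postsynaptic trace;
#' each postsynaptic spike increments `a_post` (decaying with `tau_post`)
#' and changes the weight by the current presynaptic trace. The weight is
#' updated for each complete pre/post pair; its contribution to postsynaptic
#' potentials is clipped at `w_max`, and by default the weight itself is
#' clipped below at zero.
#'
#' Two bundled parameter sets (see [stdp_params()]): `"detailed"`
#' (`A_pre = 0.3 uS`, `A_post = -0.2 uS`, `tau_post = 10 ms`) and
#' `"classic"` (`A_pre = 0.01 uS`, `A_post = -0.0105 uS`,
#' `tau_post = 20 ms`), both with `tau_pre = 20 ms`, `w0 = 1 uS`,
#' `w_max = 10 uS`.
#'
#' @param params parameter list, see [stdp_params()].
#' @return An object of class `stdp_synapse`.
#' @export
stdp_synapse <- function(params = stdp_params()) {
  structure(list(w = params$w0, a_pre = 0, a_post = 0, t_last = -Inf,
                 params = params),
            class = "stdp_synapse")
}

#' STDP parameter sets
#'
#' @param preset `"detailed"` or `"classic"` (the classical-curve set).
#' @param ... overrides for individual parameters.
#' @return Parameter list with elements `w0`, `tau_pre`, `tau_post`, `A_pre`,
#'   `A_post`, `w_max` (uS and ms), and `clip_low` (clip weight at 0).
#' @export
stdp_params <- function(preset = c("detailed", "classic"), ...) {
  preset <- match.arg(preset)
  p <- if (preset == "detailed") {
    list(w0 = 1.0, tau_pre = 20, tau_post = 10, A_pre = 0.3, A_post = -0.2,
         w_max = 10, clip_low = TRUE)
  } else {
    list(w0 = 1.0, tau_pre = 20, tau_post = 20, A_pre = 0.01,
         A_post = -0.0105, w_max = 10, clip_low = TRUE)
  }
  utils::modifyList(p, list(...))
}

#' Apply a pre- or postsynaptic spike to an STDP synapse
#'
#' Traces are decayed analytically to the spike time (`a <- a exp(-dt/tau)`,
#' exact for the linear trace dynamics); then a presynaptic spike adds the
#' postsynaptic trace to the weight and bumps `a_pre` by `A_pre`, and vice
#' versa for a postsynaptic spike.
#'
#' @param syn an [stdp_synapse()].
#' @param t spike time (ms); must not precede the last update.
#' @param kind `"pre"` or `"post"`.
#' @return Updated synapse.
#' @export
stdp_on_spike <- function(syn, t, kind = c("pre", "post")) {
  kind <- match.arg(kind)
  if (t < syn$t_last) stop("spike time regression: t = ", t, " < ",
                           syn$t_last)
  if (is.finite(syn$t_last)) {
    d <- t - syn$t_last
    syn$a_pre <- syn$a_pre * exp(-d / syn$params$tau_pre)
    syn$a_post <- syn$a_post * exp(-d / syn$params$tau_post)
  }
  if (kind == "pre") {
    syn$w <- syn$w + syn$a_post
    syn$a_pre <- syn$a_pre + syn$params$A_pre
  } else {
    syn$w <- syn$w + syn$a_pre
    syn$a_post <- syn$a_post + syn$params$A_post
  }
  if (isTRUE(syn$params$clip_low)) syn$w <- max(0, syn$w)
  syn$t_last <- t
  syn
}

#' Conductance contributed by an STDP synapse
#'
#' @param syn an [stdp_synapse()].
#' @return `min(w, w_max)`, the weight as seen by the postsynaptic cell.
#' @export
stdp_conductance <- function(syn) min(syn$w, syn$params$w_max)

#' Closed-form STDP pair window
#'
#' Weight change for one isolated pre/post pair with timing difference
#' `dt = t_post - t_pre`: `A_pre exp(-dt / tau_pre)` for `dt > 0` and
#' `A_post exp(dt / tau_post)` for `dt < 0`. At `dt = 0` the convention
#' "pre effects before post effects" yields `A_pre` exactly.
#'
#' @param dt vector of timing differences (ms).
#' @param params see [stdp_params()].
#' @return Vector of weight changes (uS).
#' @export
stdp_window <- function(dt, params = stdp_params("classic")) {
  ifelse(dt >= 0, params$A_pre * exp(-dt / params$tau_pre),
         params$A_post * exp(dt / params$tau_post))
}

#' Event-driven simulation of one STDP pair
#'
#' Runs [stdp_on_spike()] for a single pre/post pair with timing difference
#' `dt` and returns the resulting weight change; the oracle counterpart of
#' the closed form in [stdp_window()].
#'
#' @param dt timing difference `t_post - t_pre` (ms), scalar or vector.
#' @param params see [stdp_params()].
#' @return Weight change(s) (uS).
#' @export
stdp_window_sim <- function(dt, params = stdp_params("classic")) {
  vapply(dt, function(d) {
    syn <- stdp_synapse(params)
    t_pre <- max(0, -d)
    t_post <- max(0, d)
    if (d >= 0) {
      syn <- stdp_on_spike(syn, t_pre, "pre")
      syn <- stdp_on_spike(syn, t_post, "post")
    } else {
      syn <- stdp_on_spike(syn, t_post, "post")
      syn <- stdp_on_spike(syn, t_pre, "pre")
    }
    syn$w - params$w0
  }, numeric(1))
}
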