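#' Calcium-based bistable synapse
#'
#' The calcium-based plasticity model with a bistable weight: the weight
#' obeys
#' `tau_w dw/dt = -w (1-w) (w* - w) + gamma_p (1-w) H[c - theta_p]
#'  - gamma_d w H[c - theta_d] + xi(t)`,
#' where the postsynaptic calcium `c` decays with `tau_c` and jumps by
#' `c_pre` at `t_pre + tc_delay` (delayed presynaptic influx) and by
#' `c_post` at each postsynaptic spike. The noise `xi` is active only while
#' calcium exceeds a threshold and is realized as
#' `sigma_pl sqrt(tau_w (H_p + H_d)) Gamma(t)` with white noise `Gamma` of
#' variance `1/dt` (an Euler-Maruyama increment scaled by `1/dt`).
#'
#' @param params see [gb_params()].
#' @param w0 initial weight; the protocol draws it from `{0, 1}`.
#' @return An object of class `gb_synapse`.
#' @export
gb_synapse <- function(params = gb_params(), w0 = 0) {
  structure(list(w = w0, c = 0, t = 0, pending = numeric(0),
                 params = params),
            class = "gb_synapse")
}

#' Parameters of the calcium-based bistable model
#'
#' Defaults (dimensionless weight, hippocampal-slice fit): `w_star = 0.5`,
#' `tc_delay = 13.7 ms`, `c_pre = 1`, `c_post = 2`, `tau_c = 20 ms`,
#' `tau_w = 150 s`, `gamma_p = 321.808`, `gamma_d = 200`, `theta_p = 1.3`,
#' `theta_d = 1`, `sigma_pl = 2.8248`.
#'
#' @param ... overrides.
#' @return Parameter list (times in ms).
#' @export
gb_params <- function(...) {
  utils::modifyList(
    list(w_star = 0.5, tc_delay = 13.7, c_pre = 1, c_post = 2,
         tau_c = 20, tau_w = 150000, gamma_p = 321.808, gamma_d = 200,
         theta_p = 1.3, theta_d = 1, sigma_pl = 2.8248),
    list(...))
}

#' Register a spike at a calcium-based synapse
#'
#' A postsynaptic spike raises calcium by `c_post` immediately; a
#' presynaptic spike schedules an influx of `c_pre` at `t + tc_delay`
#' (an internal delayed event, not a concentration buffer).
#'
#' @param syn a [gb_synapse()].
#' @param t spike time (ms, not before the synapse clock).
#' @param kind `"pre"` or `"post"`.
#' @return Updated synapse.
#' @export
gb_on_spike <- function(syn, t, kind = c("pre", "post")) {
  kind <- match.arg(kind)
  if (t < syn$t) stop("spike time regression")
  if (kind == "post") {
    syn <- .gb_advance_calcium(syn, t)
    syn$c <- syn$c + syn$params$c_post
  } else {
    syn$pending <- sort(c(syn$pending, t + syn$params$tc_delay))
  }
  syn
}

# decay calcium analytically to time t, applying due delayed influxes
.gb_advance_calcium <- function(syn, t) {
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

#' One Euler-Maruyama step of the calcium-based synapse
#'
#' The weight drift (cubic bistability plus threshold-gated
#' potentiation/depression) is evaluated jointly at the step start; the
#' noise term is active only while calcium exceeds a threshold. Calcium is
#' then advanced analytically over the step, applying any scheduled delayed
#' presynaptic influx at its exact time.
#'
#' @param syn a [gb_synapse()].
#' @param dt step size (ms, > 0).
#' @param stream optional [noise_stream()]; `NULL` disables the noise term.
#' @return Updated synapse (clock advanced by `dt`).
#' @export
gb_step <- function(syn, dt, stream = NULL) {
  if (dt <= 0) stop("dt must be positive")
  p <- syn$params
  w <- syn$w
  hp <- as.numeric(syn$c >= p$theta_p)
  hd <- as.numeric(syn$c >= p$theta_d)
  drift <- -w * (1 - w) * (p$w_star - w) + p$gamma_p * (1 - w) * hp -
    p$gamma_d * w * hd
  w <- w + drift * dt / p$tau_w
  if (!is.null(stream) && (hp + hd) > 0) {
    w <- w + p$sigma_pl * sqrt((hp + hd) / p$tau_w) *
      sqrt(dt) * .stream_normal(stream)
  }
  syn$w <- w
  .gb_advance_calcium(syn, syn$t + dt)
}

#' Pairing-protocol curve of the calcium-based model
#'
#' For each timing difference `dt_pair = t_post - t_pre`, applies the
#' standard pairing protocol (`n_pairs` pre/post pairs presented at
#' `pair_rate`), with the initial weight drawn uniformly from `{0, 1}` per
#' trial, and accumulates the mean weight change `w_end - w_start` across
#' trials (the protocol observable; a 95% normal confidence band is
#' returned alongside).
#'
#' @param dt_grid timing differences (ms), non-empty.
#' @param n_pairs number of spike pairs (default 60).
#' @param pair_rate pair presentation rate (Hz, default 1).
#' @param n_trials trials per timing difference (>= 1).
#' @param params [gb_params()].
#' @param seed global seed for the per-trial noise streams.
#' @param dt integration step (ms).
#' @param noise logical; simulate with plasticity noise (default) or not.
#' @return Data frame `dt`, `mean_dw`, `ci_lo`, `ci_hi`.
#' @export
gb_dp_curve <- function(dt_grid, n_pairs = 60, pair_rate = 1, n_trials = 100,
                        params = gb_params(), seed = 1, dt = 1, noise = TRUE) {
  if (!length(dt_grid)) stop("dt_grid must be non-empty")
  if (n_trials < 1) stop("n_trials must be at least 1")
  out <- data.frame(dt = dt_grid, mean_dw = NA_real_, ci_lo = NA_real_,
                    ci_hi = NA_real_)
  for (k in seq_along(dt_grid)) {
    res <- .gb_protocol(dt_grid[k], n_pairs, pair_rate, n_trials, params,
                        seed, dt, noise)
    dw <- res$w_end - res$w_start
    m <- mean(dw)
    se <- stats::sd(dw) / sqrt(n_trials)
    out$mean_dw[k] <- m
    out$ci_lo[k] <- m - 1.96 * se
    out$ci_hi[k] <- m + 1.96 * se
  }
  out
}

# compiled pairing protocol (all trials of one timing difference)
.gb_protocol <- function(dt_pair, n_pairs, pair_rate, n_trials, params,
                         seed, dt, noise) {
  t_pre <- (seq_len(n_pairs) - 1) * 1000 / pair_rate
  t_post <- t_pre + dt_pair
  t_pre <- t_pre - min(0, dt_pair)   # keep all times non-negative
  t_post <- t_post - min(0, dt_pair)
  t_end <- max(t_pre, t_post) + 500
  res <- .gb_protocol_cpp(t_pre, t_post, as.numeric(unlist(params[
    c("w_star", "tc_delay", "c_pre", "c_post", "tau_c", "tau_w",
      "gamma_p", "gamma_d", "theta_p", "theta_d", "sigma_pl")])),
    n_trials, seed, dt, t_end, noise)
  res
}
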