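#' Counter-based noise streams
#'
#' A noise stream addresses an independent source of white noise by a key
#' tuple `(seed, cell, mechanism, variable)` and a step counter. The
#' underlying generator is Threefry-4x64 (12 rounds), a stateless
#' counter-based bijection: the same `(key, counter)` pair always yields the
#' same four uniform variates, on any platform, which makes every simulation
#' a pure function of its configuration and global seed. Four uniforms are
#' produced per generator invocation and cached; the counter advances by
#' exactly one when the cache is depleted.
#'
#' @param seed global seed (non-negative integer).
#' @param cell cell identifier (non-negative integer).
#' @param mechanism mechanism identifier (non-negative integer).
#' @param variable per-mechanism variable index (non-negative integer).
#' @param counter initial counter value (non-negative integer).
#' @return An object of class `noise_stream` (mutable environment).
#' @examples
#' s <- noise_stream(seed = 1)
#' draw_uniforms(s)
#' @export
noise_stream <- function(seed = 0, cell = 0, mechanism = 0, variable = 0,
                         counter = 0) {
  key <- c(seed, cell, mechanism, variable)
  if (any(!is.finite(key)) || any(key < 0) || any(key != floor(key)))
    stop("noise stream key components must be non-negative integers")
  if (counter < 0 || counter != floor(counter))
    stop("counter must be a non-negative integer")
  st <- new.env(parent = emptyenv())
  st$key <- as.numeric(key)
  st$counter <- as.numeric(counter)
  st$cache <- numeric(0)   # pending uniforms, most recent block
  st$normal_spare <- NULL  # second Box-Muller output awaiting consumption
  class(st) <- "noise_stream"
  st
}

#' @export
print.noise_stream <- function(x, ...) {
  cat(sprintf("<noise_stream key=(%s) counter=%s cached=%d>\n",
              paste(format(x$key, scientific = FALSE), collapse = ","),
              format(x$counter, scientific = FALSE), length(x$cache)))
  invisible(x)
}

# largest exactly-representable counter; well below the 2^64 counter width,
# erroring here rules out silent wraparound of the double-valued counter
.COUNTER_MAX <- 2^53 - 1

#' Draw four uniform variates from a stream
#'
#' Produces the four uniforms of the current counter block and advances the
#' counter by one. Identical `(key, counter)` pairs give bitwise-identical
#' results.
#'
#' @param stream a [noise_stream()].
#' @return Numeric vector of 4 values in `[0, 1)`.
#' @export
draw_uniforms <- function(stream) {
  stopifnot(inherits(stream, "noise_stream"))
  if (stream$counter > .COUNTER_MAX)
    stop("noise stream counter overflow (key ",
         paste(stream$key, collapse = ","), ")")
  u <- .tf_uniforms(stream$key, stream$counter)
  stream$counter <- stream$counter + 1
  u
}

# one uniform, refreshing the 4-value cache only on depletion
.stream_uniform <- function(stream) {
  if (length(stream$cache) == 0L)
    stream$cache <- draw_uniforms(stream)
  u <- stream$cache[1L]
  stream$cache <- stream$cache[-1L]
  u
}

#' Box-Muller transform of two uniforms
#'
#' Maps a pair of uniforms to a pair of independent standard normals,
#' `z1 = sqrt(-2 log u1) cos(2 pi u2)`, `z2 = sqrt(-2 log u1) sin(2 pi u2)`.
#' Both outputs are produced (no rejection), so cached uniforms are depleted
#' uniformly across noise sources. `u1 = 0` is guarded by substituting the
#' smallest positive double.
#'
#' @param u1 uniform in `(0, 1]` (0 is guarded).
#' @param u2 uniform in `[0, 1)`.
#' @return Numeric vector `c(z1, z2)`.
#' @examples
#' draw_normal_pair(0.5, 0.25)  # c(0, 1.17741...)
#' @export
draw_normal_pair <- function(u1, u2) {
  if (u1 <= 0) u1 <- .Machine$double.xmin
  r <- sqrt(-2 * log(u1))
  c(r * cos(2 * pi * u2), r * sin(2 * pi * u2))
}

# one standard normal from a stream; consumes uniforms pairwise via
# Box-Muller and keeps the second output as a spare
.stream_normal <- function(stream) {
  if (!is.null(stream$normal_spare)) {
    z <- stream$normal_spare
    stream$normal_spare <- NULL
    return(z)
  }
  u1 <- .stream_uniform(stream)
  u2 <- .stream_uniform(stream)
  # map u1 into (0,1] so log() is finite without rejecting the draw
  z <- draw_normal_pair(1 - u1, u2)
  stream$normal_spare <- z[2L]
  z[1L]
}

#' Stochastic differential equation system
#'
#' Describes `dX = f(t, X) dt + sum_i g_i(t, X) dB_i` with drift `f`, `M`
#' diffusion functions `g_i`, and one independent Wiener process (one noise
#' stream) per diffusion term; the noise correlation matrix is the identity.
#' With all diffusions zero the Euler-Maruyama step reduces exactly to
#' deterministic forward Euler.
#'
#' @param state numeric state vector `X`.
#' @param drift function `f(t, x)` returning `dX/dt` (units `[X]/time`).
#' @param diffusions list of functions `g_i(t, x)` (units `[X]/sqrt(time)`);
#'   may be empty for a deterministic system.
#' @param streams list of [noise_stream()]s, one per diffusion function.
#' @return An object of class `sde_system`.
#' @export
sde_system <- function(state, drift, diffusions = list(), streams = list()) {
  stopifnot(is.numeric(state), is.function(drift), is.list(diffusions),
            is.list(streams))
  if (length(diffusions) != length(streams))
    stop("number of diffusion functions (", length(diffusions),
         ") must equal number of noise streams (", length(streams), ")")
  structure(list(state = state, drift = drift, diffusions = diffusions,
                 streams = streams),
            class = "sde_system")
}

#' One Euler-Maruyama step
#'
#' Advances the state by
#' `X(t+dt) = X(t) + f(t, X) dt + sum_i g_i(t, X) dW_i` with independent
#' Wiener increments `dW_i ~ N(0, dt)` drawn from the system's noise streams.
#'
#' @param system an [sde_system()].
#' @param t current time.
#' @param dt positive step size.
#' @return The system with updated state.
#' @export
euler_maruyama_step <- function(system, t, dt) {
  stopifnot(inherits(system, "sde_system"))
  if (dt <= 0) stop("dt must be positive")
  x <- system$state
  fx <- system$drift(t, x)
  if (any(!is.finite(fx)))
    stop("non-finite drift evaluation at t = ", t)
  xn <- x + fx * dt
  if (length(system$diffusions)) {
    sq <- sqrt(dt)
    for (i in seq_along(system$diffusions)) {
      gx <- system$diffusions[[i]](t, x)
      if (any(!is.finite(gx)))
        stop("non-finite diffusion evaluation in component ", i,
             " at t = ", t)
      dW <- .stream_normal(system$streams[[i]]) * sq
      xn <- xn + gx * dW
    }
  }
  system$state <- xn
  system
}
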