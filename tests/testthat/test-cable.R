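test_that("a passive cable at the leak reversal stays at equilibrium", {
  g <- discretize(cylinder_morphology(100, 1), 5)
  st <- membrane_state(g, v0 = -65, e_leak = -65)
  st <- step_voltage(st, g, dt = 0.5)
  expect_equal(st$v, rep(-65, g$n), tolerance = 1e-12)
})

test_that("steady-state voltage matches the cosh solution of cable theory", {
  a <- 1; L <- 200; rl <- 100; gl <- 0.3
  g <- discretize(cylinder_morphology(L, a), 2)
  st <- membrane_state(g, v0 = -65, c_m = 1, r_l = rl, g_leak = gl,
                       e_leak = -65)
  I <- 0.05
  for (k in 1:4000) st <- step_voltage(st, g, list(list(comp = 1, current = I)), dt = 1)
  lambda <- sqrt((1 / (gl * 1e-3)) * (a * 1e-4) / (2 * rl)) * 1e4  # um
  x <- cumsum(g$length) - g$length / 2
  ri <- rl / (pi * (a * 1e-4)^2)                                   # Ohm/cm
  v_theory <- (I * 1e-9) * ri * (lambda * 1e-4) *
    cosh((L - x) / lambda) / sinh(L / lambda) * 1e3                # mV
  expect_lt(max(abs((st$v + 65) - v_theory)) / max(v_theory), 0.01)
})

test_that("grid refinement changes the steady profile by less than 1%", {
  run <- function(dl) {
    g <- discretize(cylinder_morphology(100, 1), dl)
    st <- membrane_state(g, v0 = -65, e_leak = -65)
    for (k in 1:2000) st <- step_voltage(st, g, list(list(comp = 1, current = 0.05)), dt = 1)
    st$v[g$n]   # distal potential
  }
  v1 <- run(4); v2 <- run(2)
  expect_lt(abs(v1 - v2) / abs(v2 + 65), 0.01)
})

test_that("Hodgkin-Huxley soma fires periodically, robust to dt halving", {
  count_spikes <- function(dt) {
    g <- discretize(cylinder_morphology(20, 10, tag = "soma"), 20)
    st <- membrane_state(g, v0 = -65, g_leak = 0.3, e_leak = -54.4,
                         hh_comps = 1)
    n <- 0; vprev <- st$v[1]
    for (k in seq_len(round(400 / dt))) {
      st <- step_voltage(st, g, list(list(comp = 1, current = 0.2)), dt)
      if (vprev < 0 && st$v[1] >= 0) n <- n + 1
      vprev <- st$v[1]
    }
    n
  }
  n1 <- count_spikes(0.025)
  n2 <- count_spikes(0.0125)
  expect_gt(n1, 10)                 # sustained periodic spiking
  expect_lte(abs(n1 - n2), 1)       # spike count stable under dt halving
})

test_that("diffusion with zero diffusivity and sources leaves the field alone", {
  set.seed(2)
  g <- discretize(cylinder_morphology(50, 1), 1)
  f <- species_field(g, conc = runif(g$n), D = 0)
  f2 <- step_diffusion(f, g, 1)
  expect_equal(f2$conc, f$conc, tolerance = 1e-12)
  expect_error(species_field(g, D = -1), "non-negative")
  expect_error(step_diffusion(f, g, 0), "dt")
})

test_that("a point deposit spreads as the 1-D Gaussian", {
  g <- discretize(cylinder_morphology(400, 1), 1)
  f <- species_field(g, conc = 0, D = 2.2e-10)
  f$conc[200] <- 100
  dt <- 0.1
  for (k in 1:500) f <- step_diffusion(f, g, dt)
  D <- 2.2e-10 * 1e9; tt <- 50
  x <- (cumsum(g$length) - g$length / 2) - 199.5
  theory <- 100 / sqrt(4 * pi * D * tt) * exp(-x^2 / (4 * D * tt))
  sel <- abs(x) < 3 * sqrt(2 * D * tt)    # before boundary influence
  expect_lt(max(abs(f$conc[sel] - theory[sel])) / max(theory), 0.02)
})

test_that("total amount is conserved to 1e-10 over a thousand steps", {
  segs <- data.frame(id = 1:3, parent = c(NA, 1L, 1L),
                     prox_radius = c(1, 0.8, 1.2), dist_radius = c(1, 0.6, 1),
                     length = c(40, 25, 30), tag = "dendrite")
  g <- discretize(morphology(segs), 1)
  set.seed(3)
  f <- species_field(g, conc = runif(g$n), D = 5e-10)
  a0 <- total_amount(f, g)
  for (k in 1:1000) f <- step_diffusion(f, g, 0.5)
  expect_lt(abs(total_amount(f, g) - a0) / a0, 1e-10)
  expect_true(all(f$conc >= 0))
})

test_that("the implicit step matches a fine explicit oracle", {
  g <- discretize(cylinder_morphology(20, 1), 1)
  f <- species_field(g, conc = c(rep(1, 5), rep(0, 15)), D = 2.2e-10)
  gd <- f$D * g$a_center[1] / 1   # uniform grid coupling, um^3/ms
  dt <- 0.004                     # implicit step; oracle runs at dt/1000
  oracle <- explicit_diffusion_oracle(f$conc, g$volume, rep(gd, g$n - 1),
                                      dt = dt / 1000, n_steps = 250000)
  for (k in 1:250) f <- step_diffusion(f, g, dt)
  expect_lt(sqrt(sum((f$conc - oracle)^2) / sum(oracle^2)), 1e-4)
})

test_that("the implicit solvers stay bounded at millisecond steps", {
  sp <- morpho_cell_spec("small", "long")
  f <- species_field(sp$grid, conc = 10, D = 1e-9)
  st <- membrane_state(sp$grid, v0 = -60)
  for (k in 1:200) {
    f <- step_diffusion(f, sp$grid, 1)
    st <- step_voltage(st, sp$grid, list(list(comp = 1, current = 0.5)), 1)
  }
  expect_true(all(is.finite(f$conc)) && max(f$conc) <= 10 + 1e-9)
  expect_true(all(is.finite(st$v)) && max(abs(st$v)) < 200)
})
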