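test_that("the printed thresholds are the stated functions of the rates", {
  p <- stc_params()
  expect_equal(0.5 * p$gamma_p / (p$gamma_p + p$gamma_d) * 10, p$h0,
               tolerance = 1e-5)   # agreement at the printed precision
  expect_equal(0.5 * p$h0, p$theta_pro, tolerance = 1e-5)
  expect_equal(0.2 * p$h0, p$theta_tag, tolerance = 1e-5)
  pv <- stc_params(in_vivo = TRUE)
  expect_equal(pv$c_pre, 0.6)
  expect_equal(pv$c_post, 0.1655, tolerance = 1e-3)
})

test_that("h0 is a fixed point and sustained calcium drives h to the drift root", {
  p <- stc_params()
  syn <- stc_synapse(p)
  pool <- prp_pool(p)
  for (k in 1:100) syn <- stc_step(syn, pool, 1)$syn
  expect_equal(syn$h, p$h0)
  syn <- stc_synapse(p)
  syn$params$tau_c <- 1e18
  syn$c <- 100
  for (k in 1:5000) syn <- stc_step(syn, pool, 10)$syn
  h_star <- (0.1 * p$h0 + 10 * p$gamma_p) / (0.1 + p$gamma_p + p$gamma_d)
  expect_equal(syn$h, h_star, tolerance = 1e-6)
  expect_equal(h_star, 8.402, tolerance = 1e-3)
  # fine-step oracle agreement on the approach
  syn2 <- stc_synapse(p); syn2$params$tau_c <- 1e18; syn2$c <- 100
  for (k in 1:10000) syn2 <- stc_step(syn2, pool, 1)$syn
  oracle <- stc_drift_oracle(p$h0, 1, 1, t_span = 10000, dt = 0.01, p)
  expect_lt(abs(syn2$h - oracle) / oracle, 1e-4)
})

test_that("delayed presynaptic calcium and tagging behave per the rule", {
  p <- stc_params()
  syn <- stc_on_spike(stc_synapse(p), 0, "pre")
  expect_equal(plastnet:::.stc_advance_calcium(syn, 18.7)$c, 0)
  expect_equal(plastnet:::.stc_advance_calcium(syn, 18.8)$c, p$c_pre)
  post <- stc_on_spike(stc_synapse(p), 0, "post")
  expect_equal(post$c, p$c_post)
})

test_that("a tagged synapse with a full pool approaches z = 1 with tau_z", {
  p <- stc_params()
  syn <- stc_synapse(p)
  syn$h <- p$h0 + 2 * p$theta_tag       # tagged for potentiation
  pool <- prp_pool(p, p = p$p_max)      # p_max f_int = 1: dz/dt = (1-z)/tau_z
  z_prev <- 0
  dt <- 1000
  s <- stc_step(syn, pool, dt)
  expect_equal(s$syn$z, dt / p$tau_z * (1 - 0), tolerance = 1e-9)
  # closed form over an hour
  syn$z <- 0
  n <- 3600
  for (k in seq_len(n)) {
    s <- stc_step(syn, pool, 1000)
    syn$h <- p$h0 + 2 * p$theta_tag     # hold the tag
    syn$z <- s$syn$z
  }
  expect_equal(syn$z, 1 - (1 - 1000 / p$tau_z)^n, tolerance = 1e-6)
  expect_equal(1 - exp(-3600e3 / p$tau_z), syn$z, tolerance = 1e-3)
})

test_that("the protein pool decays with tau_p and saturates at p_max", {
  p <- stc_params()
  pool <- prp_pool(p, p = 0)
  pool <- prp_step(pool, sum_dev = 0, dt = 1000)
  expect_equal(pool$p, 0)
  pool$p <- 4
  pool <- prp_step(pool, sum_dev = 0, dt = p$tau_p)
  expect_equal(pool$p, 4 * exp(-1), tolerance = 1e-9)
  pool$p <- 0
  for (k in 1:800) pool <- prp_step(pool, sum_dev = 10, dt = 60000)
  expect_equal(pool$p, p$p_max, tolerance = 1e-3)
  expect_true(pool$p <= p$p_max)
})

test_that("noisy trials respect the state bounds", {
  p <- stc_params()
  ok <- TRUE
  for (tr in 1:50) {
    res <- stc_single_run(pre_times = seq(0, 490, by = 10), t_end = 2000,
                          seed = 21, trial = tr, dt = 0.5, noise = TRUE,
                          record_every = 0)
    st <- res$state
    ok <- ok && st[1] >= 0 && st[1] <= 10 &&      # h in [0, 10]
      st[2] >= -0.5 && st[2] <= 1 &&              # z in [-0.5, 1]
      st[4] >= 0 && st[4] <= p$p_max              # p in [0, p_max]
  }
  expect_true(ok)
})

test_that("the four induction protocols produce their canonical outcomes", {
  stet <- stc_protocol("STET", seed = 3, noise = TRUE, record_every = 0)
  expect_true(stet$crossed_tag && stet$crossed_pro)
  expect_gt(stet$z_end, 0.5)
  wtet <- stc_protocol("WTET", seed = 3, noise = TRUE, record_every = 0)
  expect_true(wtet$crossed_tag)
  expect_false(wtet$crossed_pro)
  expect_lt(abs(wtet$z_end), 0.05)
  wlfs <- stc_protocol("WLFS", seed = 3, noise = TRUE, record_every = 0)
  expect_lt(wlfs$h_after_stim, stc_params()$h0)
  expect_lt(abs(wlfs$z_end), 0.05)
  slfs <- stc_protocol("SLFS", seed = 3, noise = TRUE, record_every = 0)
  expect_true(slfs$crossed_tag && slfs$crossed_pro)
  expect_lt(slfs$z_end, -0.1)           # late-phase depression
  expect_error(stc_protocol("XXXX"), "STET")
})

test_that("fast-forward relaxation follows the closed-form exponential", {
  p <- stc_params()
  h_start <- p$h0 + 0.5   # below both the tag and synthesis thresholds
  ff <- stc_fast_forward(h = h_start, z = 0.3, p = 0, t_span = 3600e3,
                         params = p)
  expect_equal(ff$z, 0.3)  # untagged: late phase frozen
  expect_equal(ff$h, p$h0 + 0.5 * exp(-0.1 * 3600e3 / p$tau_h),
               tolerance = 1e-6)
  expect_equal(ff$p, 0)    # below theta_pro: no synthesis
})
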