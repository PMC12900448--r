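test_that("the spine source term is zero without spikes and linear in them", {
  hp <- hetero_params()
  hm <- hetero_morphology(hp)
  f0 <- species_field(hm$grid, "ca", D = hp$d_ca, decay_tau = hp$tau_c)
  f <- spine_calcium_source(f0, hm$grid, hm$spine_comp[1], w = 1,
                            spike_times = numeric(0), t = 0, dt = 0.1,
                            params = hp)
  expect_true(all(f$source == 0))
  one_a <- spine_calcium_source(f0, hm$grid, hm$spine_comp[1], 1, 0, 5, 0.1, hp)
  one_b <- spine_calcium_source(f0, hm$grid, hm$spine_comp[1], 1, 10, 5, 0.1, hp)
  both <- spine_calcium_source(f0, hm$grid, hm$spine_comp[1], 1, c(0, 10), 5, 0.1, hp)
  expect_equal(both$source, one_a$source + one_b$source, tolerance = 1e-12)
  expect_error(spine_calcium_source(f0, hm$grid, 10000, 1, 0, 0, 0.1, hp),
               "not on the grid")
})

test_that("time-integrated calcium delivery equals gamma I0 tau_I / 2F", {
  hp <- hetero_params(i0 = 4.0)         # unit-conversion contract
  hm <- hetero_morphology(hp)
  grid <- hm$grid
  comp <- hm$spine_comp[1]
  # accumulate source over many small steps after one spike at t = 0
  dt <- 0.01
  total_umol <- 0
  f0 <- species_field(grid, "ca", D = 0)
  for (k in seq_len(2000)) {             # 20 ms >> tau_i = 1 ms
    f <- spine_calcium_source(f0, grid, comp, 1, 0, (k - 1) * dt, dt, hp)
    total_umol <- total_umol + f$source[comp] * grid$volume[comp] * 1e-15 * dt
  }
  expected_mol <- hp$gamma_ca * hp$i0 * 1e-12 * hp$tau_i * 1e-3 /
    (2 * 96485.33212)
  expect_equal(total_umol * 1e-6, expected_mol, tolerance = 1e-6)
  # numeric quadrature of the current waveform agrees
  tt <- seq(0, 20, by = 1e-3)
  quad <- sum(hp$gamma_ca * hp$i0 * 1e-12 * exp(-tt / hp$tau_i)) * 1e-3 * 1e-3 /
    (2 * 96485.33212)
  expect_equal(expected_mol, quad, tolerance = 1e-3)
})

test_that("weights freeze below theta_d, decay slowly between thresholds, and
           approach the potentiation fixed point above theta_p", {
  hp <- hetero_params()
  w <- c(0.5, 0.5, 0.5)
  conc <- c(0.01, 0.08, 0.5)    # below theta_d, between, above theta_p
  w1 <- hetero_weight_step(w, conc, dt = 10, hp)
  expect_equal(w1[1], 0.5)
  expect_lt(w1[2], 0.5)
  expect_equal(0.5 - w1[2], 0.5 * hp$gamma_d * 0.01, tolerance = 1e-9)
  expect_gt(w1[3], 0.5)
  # sustained supra-threshold concentration: w -> gamma_p/(gamma_p+gamma_d)
  ww <- 0.5
  for (k in 1:20000) ww <- hetero_weight_step(ww, 1, 10, hp)
  expect_equal(ww, hp$gamma_p / (hp$gamma_p + hp$gamma_d), tolerance = 1e-4)
  expect_equal(hp$gamma_p / (hp$gamma_p + hp$gamma_d), 0.99989, tolerance = 1e-4)
})

test_that("stimulating spines 1 and 3 potentiates spines 1-3 and depresses spine 4", {
  res <- run_hetero_experiment(dt = 0.2, stim_duration = 1000,
                               duration = 2500)
  w0 <- hetero_params()$w_init
  expect_true(all(res$w_end[1:3] > w0 + 0.2))
  expect_lt(res$w_end[4], w0)
  # dendritic locations between spines show transient elevation above baseline
  expect_true(all(apply(res$conc_dendrite, 2, max) > 0.02))
  # and the discrete mass balance (injection and decay accounted) closes
  expect_lt(res$balance_residual, 1e-8)
})

test_that("without stimulation all four weights stay constant", {
  res <- run_hetero_experiment(dt = 0.5, stim_duration = 0, duration = 200)
  expect_equal(res$w_end, rep(hetero_params()$w_init, 4))
  expect_true(all(res$conc == 0))
})
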