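test_that("network construction is Bernoulli, self-loop free, and seeded", {
  rec <- network_recipe(n = 500, n_exc = 400, p_conn = 0.1, seed = 7)
  net <- build_network(rec)
  n_ee <- length(net$p_src)
  mu <- 0.1 * 400 * 399
  expect_lt(abs(n_ee - mu), 3 * sqrt(mu * 0.9))
  expect_true(all(net$p_src != net$p_dst))
  expect_true(all(net$p_src < 400 & net$p_dst < 400))
  net2 <- build_network(rec)
  expect_identical(net$p_src, net2$p_src)
  expect_identical(net$net$s_dst, net2$net$s_dst)
  empty <- build_network(network_recipe(n = 50, n_exc = 40, p_conn = 0))
  expect_length(empty$p_src, 0)
  expect_length(empty$net$s_dst, 0)
  expect_error(network_recipe(p_conn = 1.5), "p_conn")
  expect_error(network_recipe(n = 10, n_exc = 20), "exceed")
})

test_that("normalized inhibition equalizes summed inhibitory in-weights", {
  net <- build_network(network_recipe(n = 300, n_exc = 240, seed = 5))
  w <- net$net$s_w
  dst <- net$net$s_dst
  inh <- w < 0 & dst < 240           # inhibitory inputs to excitatory cells
  tot <- tapply(w[inh], dst[inh], sum)
  expect_lt(stats::sd(tot) / abs(mean(tot)), 1e-12)
})

test_that("the pattern completion coefficient is the stated rate ratio", {
  mk <- function(r_as, r_ans, r_ctrl) {
    t <- c(seq(0, 499, length.out = r_as * 5),      # 10 'as' neurons, 0.5 s
           seq(0, 499, length.out = r_ans * 5),
           seq(0, 499, length.out = r_ctrl * 5))
    gid <- c(rep(1:10, length.out = r_as * 5),
             rep(11:20, length.out = r_ans * 5),
             rep(21:30, length.out = r_ctrl * 5))
    list(t = t, gid = gid)
  }
  sub <- list(as = 1:10, ans = 11:20, ctrl = 21:30)
  expect_equal(compute_Q(mk(8, 6, 2), sub, 250), 0.5)
  expect_equal(compute_Q(mk(8, 4, 4), sub, 250), 0)
  silent <- list(t = c(100, 200), gid = c(11, 25))
  expect_error(compute_Q(silent, sub, 250), "silent")
  # dimensionless: invariant under uniform rescaling of all rates
  expect_equal(compute_Q(mk(16, 12, 4), sub, 250), 0.5)
})

test_that("the renormalized synthesis threshold divides by total volume", {
  g1 <- point_neuron_grid(r_comp = 2, l_cell = 4)
  expect_equal(renormalized_threshold(2.10037, g1), 2.10037 / (pi * 4 * 4))
  sp <- morpho_cell_spec("small", "long")
  vtot <- sum(vapply(seq_len(sp$grid$n), function(i) sp$grid$volume[i],
                     numeric(1)))
  expect_equal(renormalized_threshold(1, sp$grid), 1 / vtot)
  thin <- discretize(cylinder_morphology(40, 2), 1)
  thick <- discretize(cylinder_morphology(40, 4), 1)  # double radius: V x4
  expect_equal(renormalized_threshold(1, thick) /
                 renormalized_threshold(1, thin), 1 / 4, tolerance = 1e-12)
})

test_that("splitting a run at a phase boundary leaves the raster identical", {
  rec <- network_recipe(n = 60, n_exc = 48, seed = 9)
  a <- run_phases(build_network(rec), list(list(mode = "full", t_end = 2000)))
  b <- run_phases(build_network(rec),
                  list(list(mode = "full", t_end = 1000),
                       list(mode = "ff", t_end = 1000),
                       list(mode = "full", t_end = 2000)))
  expect_identical(a$raster, b$raster)
  expect_equal(a$state$h, b$state$h)
  expect_equal(a$state$v, b$state$v)
  expect_error(run_phases(a, list(list(mode = "full", t_end = 100))),
               "contiguous")
})

test_that("fast-forward advances only the slow variables, in closed form", {
  rec <- network_recipe(n = 60, n_exc = 48, seed = 9)
  net <- build_network(rec)
  pl <- rec$plasticity
  net$state$h[] <- pl$h0 + 0.1   # below the tag threshold, and small
                                 # enough that no neuron's summed deviation
                                 # reaches the synthesis threshold
  net <- run_phases(net, list(list(mode = "ff", t_end = 3600e3)))
  expect_equal(net$state$h,
               rep(pl$h0 + 0.1 * exp(-0.1 * 3600e3 / pl$tau_h),
                   length(net$state$h)), tolerance = 1e-6)
  expect_true(all(net$state$z == 0))
  expect_true(all(net$state$p == 0))
})

test_that("single-compartment tag signalling reduces to the scalar pool", {
  p <- stc_params(in_vivo = TRUE)
  spec <- list(grid = point_neuron_grid(r_comp = 1, l_cell = 2),
               soma_center = 1L, basal_tip = 1L, apical_tip = 1L)
  cell <- sps_cell(spec, p)
  pool <- prp_pool(p)
  dev_prev <- 0
  for (k in 1:50) {
    dev <- 3 * abs(sin(k / 5))          # crosses theta_pro repeatedly
    out <- sps_prp_coupling(cell, syn_comp = 1L, dev = dev,
                            dev_prev = dev_prev, dt = 100)
    cell <- out$cell
    pool <- prp_step(pool, dev, dt = 100)
    dev_prev <- dev
  }
  expect_equal(cell$prp$conc, pool$p, tolerance = 1e-9)
})

test_that("slow protein diffusion never reaches the dendrite tips", {
  # D_p = 1e-19 m^2/s on the long-dendrite cell: over 8 h the tip
  # concentration stays below 1% of p_max, so no late-phase change there
  p <- stc_params(in_vivo = TRUE)
  spec <- morpho_cell_spec("small", "long")
  cell <- sps_cell(spec, p, d_sps = 1e-11, d_p = 1e-19)
  dt <- 10e3
  dev_prev <- 0
  for (k in seq_len(8 * 360)) {          # 8 h at 10-s steps
    out <- sps_prp_coupling(cell, syn_comp = spec$basal_tip, dev = 5,
                            dev_prev = dev_prev, dt = dt)
    cell <- out$cell
    dev_prev <- 5
  }
  expect_true(cell$synthesizing)
  expect_gt(cell$prp$conc[cell$synth_comp], 0.5 * p$p_max)
  expect_lt(cell$prp$conc[spec$apical_tip], 0.01 * p$p_max)
  expect_lt(cell$prp$conc[spec$basal_tip], 0.01 * p$p_max)
})

test_that("protein amount decays with tau_p and is conserved by transport", {
  p <- stc_params(in_vivo = TRUE)
  spec <- morpho_cell_spec("small", "short")
  cell <- sps_cell(spec, p, d_p = 1e-11)
  cell$prp$conc[] <- 5                   # pre-loaded, no synthesis
  g <- spec$grid
  a0 <- sum(cell$prp$conc * g$volume)
  dt <- 1e3
  for (k in 1:100) {
    out <- sps_prp_coupling(cell, syn_comp = spec$basal_tip, dev = 0,
                            dev_prev = 0, dt = dt)
    cell <- out$cell
  }
  expect_false(cell$synthesizing)
  a1 <- sum(cell$prp$conc * g$volume)
  expect_equal(a1, a0 * exp(-100e3 / p$tau_p), tolerance = 1e-3)
})

test_that("learned assemblies are recalled: Q > 0, absent without learning", {
  res <- recall_experiment(network_recipe(seed = 2), assembly_size = 60)
  expect_gt(res$Q, 0)
  # within-assembly weights potentiated, outgoing ones not
  net <- res$network
  win <- mean(net$state$h[net$p_src < 60 & net$p_dst < 60])
  out <- mean(net$state$h[net$p_src < 60 & net$p_dst >= 60])
  expect_gt(win, 6)
  expect_lt(out, win - 1)
  res0 <- recall_experiment(network_recipe(seed = 2), learn = FALSE)
  expect_lt(abs(res0$Q), 0.05)
})
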