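test_that("single spike pairs follow the exponential pair rule", {
  p <- stdp_params("classic")   # A_pre 0.01, A_post -0.0105, tau 20/20
  # first-ever presynaptic spike: no complete pair, weight unchanged
  syn <- stdp_on_spike(stdp_synapse(p), 0, "pre")
  expect_equal(syn$w, p$w0)
  # pre at 0, post at +20 ms: dw = A_pre exp(-1)
  expect_equal(stdp_window_sim(20, p), 0.01 * exp(-1), tolerance = 1e-12)
  # post at 0, pre at +10 ms: dw = A_post exp(-0.5)
  expect_equal(stdp_window_sim(-10, p), -0.0105 * exp(-0.5), tolerance = 1e-12)
  # timing-difference limits
  expect_equal(stdp_window(1e6, p), 0)
  expect_equal(stdp_window(0, p), p$A_pre)
  expect_error(stdp_on_spike(stdp_on_spike(stdp_synapse(p), 10, "pre"), 5, "pre"),
               "regression")
})

test_that("the closed-form window equals event-driven simulation exactly", {
  for (preset in c("classic", "detailed")) {
    p <- stdp_params(preset)
    dts <- setdiff(seq(-100, 100, by = 1), 0)
    expect_lt(max(abs(stdp_window_sim(dts, p) - stdp_window(dts, p))), 1e-14)
  }
})

test_that("the conductance contribution is clipped at w_max", {
  p <- stdp_params("detailed", w_max = 2)
  syn <- stdp_synapse(p)
  syn$w <- 5
  expect_equal(stdp_conductance(syn), 2)
  # and the weight itself clips at zero by default
  syn2 <- stdp_synapse(stdp_params("detailed", w0 = 0.001))
  syn2 <- stdp_on_spike(syn2, 0, "post")
  syn2 <- stdp_on_spike(syn2, 1, "pre")   # large depression from a_post
  expect_gte(syn2$w, 0)
  # configurable: without the lower clip the weight can go negative
  syn3 <- stdp_synapse(stdp_params("detailed", w0 = 0.001, clip_low = FALSE))
  syn3 <- stdp_on_spike(syn3, 0, "post")
  syn3 <- stdp_on_spike(syn3, 1, "pre")
  expect_lt(syn3$w, 0)
})

test_that("homeostatic updates cancel, clip, and accumulate as stated", {
  p <- homeo_params()           # dw+ = 0.35, dw- = -0.35, w_max = 5
  syn <- homeo_synapse(p)
  syn <- homeo_on_spike(syn, "pre")
  syn <- homeo_on_spike(syn, "post")
  expect_equal(syn$w, 0)        # one pre + one post cancel
  syn$w <- 5
  syn <- homeo_on_spike(syn, "pre")
  expect_equal(syn$w, 5)        # clipped at w_max
  syn2 <- homeo_synapse(p)
  for (k in 1:3) syn2 <- homeo_on_spike(syn2, "pre")
  expect_equal(syn2$w, 1.05)
})

test_that("homeostasis regulates the output rate to the plastic input rate", {
  res <- run_homeostasis_experiment(duration = 30000,
                                    stream_pre = noise_stream(seed = 8, mechanism = 1),
                                    stream_var = noise_stream(seed = 8, mechanism = 2))
  expect_lt(abs(mean_rate_outside_silence(res) - 50) / 50, 0.1)
  # weight stays within bounds throughout
  expect_true(all(res$weight$w >= 0 & res$weight$w <= 5))
})

test_that("without plasticity the output follows the varying input instead", {
  res <- run_homeostasis_experiment(duration = 30000, plasticity = FALSE,
                                    stream_pre = noise_stream(seed = 8, mechanism = 1),
                                    stream_var = noise_stream(seed = 8, mechanism = 2))
  sched <- res$schedule[res$schedule$t1 <= 30000, ]
  rates <- vapply(seq_len(nrow(sched)), function(k)
    res$rate_fn(sched$t0[k], sched$t1[k]), numeric(1))
  # output rises and falls with the input rate rather than holding 50 Hz
  expect_gt(stats::cor(rates, sched$rate), 0.9)
  expect_gt(max(abs(rates - 50)), 10)
})

test_that("the Poisson-driven STDP experiment exercises the dispatch hook", {
  res <- run_stdp_experiment(duration = 2000, seed = 2)
  expect_gt(res$counters$n_pre, 20)
  expect_equal(res$counters$n_post, length(res$t_post))
  expect_true(is.finite(res$synapse$w))
  expect_gt(nrow(res$trace), 10)
})
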