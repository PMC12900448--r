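test_that("Poisson spike trains have Poisson statistics and are reproducible", {
  expect_identical(poisson_spikes(0, 0, 1000, noise_stream(1)), numeric(0))
  expect_error(poisson_spikes(-1, 0, 1000, noise_stream(1)), "non-negative")
  s1 <- noise_stream(seed = 4, mechanism = 2)
  s2 <- noise_stream(seed = 4, mechanism = 2)
  t1 <- poisson_spikes(20, 0, 5000, s1)
  expect_identical(t1, poisson_spikes(20, 0, 5000, s2))
  expect_true(all(diff(t1) > 0) && all(t1 >= 0 & t1 < 5000))
  # 200 trials of 100 Hz over 10 s: mean count within 3 sigma of 1000
  counts <- vapply(1:200, function(k)
    length(poisson_spikes(100, 0, 10000, noise_stream(seed = 4, cell = k))),
    numeric(1))
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000))
})

test_that("regular trains have exact interval spacing", {
  tr <- regular_spikes(10, 0, 100)
  expect_equal(tr, seq(0, 90, by = 10))
  expect_error(regular_spikes(0, 0, 100), "interval")
})

test_that("constant suprathreshold drive gives the closed-form LIF interval", {
  nrn <- lif_neuron(v_rest = -65, v_reset = -70, v_thresh = -55, tau_m = 10,
                    r_m = 10, t_ref = 2)
  I <- 2.0   # nA: v_inf = -45 mV, suprathreshold
  dt <- 0.01
  spikes <- c()
  for (k in seq_len(round(100 / dt))) {
    st <- lif_step(nrn, list(current = I), dt)
    nrn <- st$neuron
    if (st$spiked) spikes <- c(spikes, k * dt)
  }
  v_inf <- -65 + 10 * I
  t_cross <- 10 * log((v_inf + 70) / (v_inf + 55))
  expect_lt(abs(mean(diff(spikes)) - (2 + t_cross)), 2 * dt)
})

test_that("input during the refractory period can never elicit a spike", {
  nrn <- lif_neuron()
  st <- lif_step(nrn, list(jump = 100), 0.1)      # forced spike
  expect_true(st$spiked)
  st2 <- lif_step(st$neuron, list(jump = 1e6), 0.1)
  expect_false(st2$spiked)
  expect_equal(st2$neuron$v, nrn$v_reset)
  # and a resting neuron with no input stays silent at rest
  st3 <- lif_step(lif_neuron(), list(), 1)
  expect_false(st3$spiked)
  expect_equal(st3$neuron$v, -65)
})

test_that("the event queue delivers in time order with stable ties", {
  q <- event_queue()
  queue_push(q, 5, "a")
  queue_push(q, 2, "b")
  queue_push(q, 5, "c")
  queue_push(q, 9, "d")
  expect_identical(unlist(queue_pop_due(q, 5)), c("b", "a", "c"))
  expect_identical(unlist(queue_pop_due(q, 10)), "d")
  expect_length(queue_pop_due(q, 99), 0)
  ev <- spike_event(1, c(2, 1), t_emit = 10, delay = 3)
  expect_equal(ev$t_deliver, 13)
  expect_error(spike_event(1, 2, 0, delay = -1), "delay")
})

test_that("a postsynaptic spike fans out to every attached mechanism once", {
  counts <- new.env()
  counts$a <- 0; counts$b <- 0; counts$t <- numeric(0)
  mech <- function(slot) list(on_post = function(m, t) {
    counts[[slot]] <- counts[[slot]] + 1
    counts$t <- c(counts$t, t)
    m
  })
  cell <- list(mechanisms = list(mech("a"), mech("b"), mech("a")))
  cell <- post_event_dispatch(cell, 37.5)
  expect_equal(counts$a, 2)          # two co-located mechanisms of one kind
  expect_equal(counts$b, 1)
  expect_true(all(counts$t == 37.5)) # all observe the same spike time
})

test_that("a two-neuron chain responds exactly one delay after the source", {
  # delta-synapse chain driven through the event queue at fixed dt
  dt <- 0.1; delay <- 3
  q <- event_queue()
  pre_spike <- 5
  queue_push(q, pre_spike + delay, list(gid = 2, w = 20))
  nrn <- lif_neuron()
  t_fire <- NA
  for (k in seq_len(200)) {
    t <- k * dt
    due <- queue_pop_due(q, t)
    jump <- sum(vapply(due, function(e) e$w, numeric(1)))
    st <- lif_step(nrn, list(jump = jump), dt)
    nrn <- st$neuron
    if (st$spiked && is.na(t_fire)) t_fire <- t
  }
  expect_lt(abs(t_fire - (pre_spike + delay)), dt + 1e-9)
})
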