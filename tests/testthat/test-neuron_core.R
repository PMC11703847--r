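test_that("synaptic drive follows the ohmic driving force", {
  # no input and zero driving force both give zero current
  expect_equal(synaptic_drive(rep(0, 5), rep(-0.07, 5), 0), rep(0, 5))
  expect_equal(synaptic_drive(c(1e-9, 2e-9), rep(-0.06, 2), -0.06),
               c(0, 0))
  # 1 nS at -70 mV toward 0 mV is 70 pA
  expect_equal(synaptic_drive(1e-9, -70e-3, 0), 70e-12)
  # sign follows the driving force
  expect_lt(synaptic_drive(1e-9, -70e-3, -80e-3), 0)
  expect_error(synaptic_drive(c(1e-9, 1e-9, 1e-9), c(-0.07, -0.07), 0),
               "dimension")
})

test_that("membrane is at a fixed point at rest and relaxes exponentially", {
  p <- neuron_params(noise_sd = 0)
  st <- layer_state(3, p)
  st2 <- integrate_step(st, 0, 0, p)
  expect_equal(st2$v, st$v)   # V = E is a fixed point of the leak term

  # leak-only relaxation from a displaced start matches the closed-form
  # exponential within the Euler error bound, and halving the step
  # halves the maximal deviation (first-order convergence)
  relax <- function(dt, t_end = 5 * p$tau) {
    st <- layer_state(1, p)
    st$v <- -60e-3
    n <- round(t_end / dt)
    path <- numeric(n)
    for (i in seq_len(n)) {
      st <- integrate_step(st, 0, 0, p, dt = dt)
      path[i] <- st$v
    }
    exact <- p$e_leak + (-60e-3 - p$e_leak) * exp(-seq_len(n) * dt / p$tau)
    max(abs(path - exact))
  }
  err1 <- relax(p$tau / 20)
  err2 <- relax(p$tau / 40)
  expect_lt(err1, 1e-3)
  expect_gt(err1 / err2, 1.6)  # ~2 for a first-order scheme
  expect_lt(err1 / err2, 2.4)
})

test_that("refractory neurons stay clamped and count down", {
  p <- neuron_params(noise_sd = 0)
  st <- layer_state(1, p)
  st$refractory_remaining <- 2L
  st$v <- -55e-3
  st2 <- integrate_step(st, 1e-9, 0, p)
  expect_equal(st2$v, p$v_reset)
  expect_equal(st2$refractory_remaining, 1L)
})

test_that("non-finite inputs are rejected with the neuron index", {
  p <- neuron_params(noise_sd = 0)
  st <- layer_state(3, p)
  expect_error(integrate_step(st, c(0, NaN, 0), 0, p), "index 2")
})

test_that("spike reset fires exactly the above-threshold set", {
  p <- neuron_params(noise_sd = 0)
  st <- layer_state(1, p)
  st$v <- -70e-3
  st <- apply_spike_reset(st, p)
  expect_false(any(st$spiked))
  expect_equal(st$v, -70e-3)

  st$v <- -49e-3
  st <- apply_spike_reset(st, p)
  expect_true(st$spiked)
  expect_equal(st$v, p$v_reset)
  expect_equal(st$refractory_remaining, p$refractory_steps)

  # brute-force set comparison on random voltages
  set.seed(7)
  stn <- layer_state(100, p)
  stn$v <- runif(100, -80e-3, -30e-3)
  expected <- which(stn$v > p$v_th)
  stn <- apply_spike_reset(stn, p)
  expect_equal(which(stn$spiked), expected)
})

test_that("a neuron never spikes twice within its refractory period", {
  p <- neuron_params(noise_sd = 0, refractory_steps = 3L)
  st <- layer_state(1, p)
  spikes <- integer(0)
  for (t in 1:60) {
    st <- integrate_step(st, 5e-9, 0, p)   # strong tonic drive
    st <- apply_spike_reset(st, p)
    if (st$spiked) spikes <- c(spikes, t)
  }
  expect_gt(length(spikes), 2)
  expect_true(all(diff(spikes) > p$refractory_steps))
})

test_that("voltages stay within the reversal-bounded range under load", {
  p <- neuron_params(noise_sd = 0)
  set.seed(1)
  st <- layer_state(20, p)
  for (t in 1:200) {
    st <- integrate_step(st, runif(20, 0, 3e-9), -runif(20, 0, 3e-9), p)
    st <- apply_spike_reset(st, p)
    expect_true(all(st$v >= min(p$e_inh, p$v_reset) - 1e-12))
    expect_true(all(st$v <= p$v_peak + 1e-12))
  }
})
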