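test_that("soft bounds annihilate increments at the rails", {
  p <- stdp_params()
  expect_equal(stdp_delta(p$w_max, -3, p), 0)
  expect_equal(stdp_delta(p$w_min, 2, p), 0)
})

test_that("pair increments match the closed-form rule on a grid", {
  p <- stdp_params(w_min = 0, w_max = 4)
  grid <- expand.grid(w = seq(0, 4, by = 0.5), dt = -20:20)
  got <- stdp_delta(grid$w, grid$dt, p)
  want <- mapply(stdp_oracle, grid$w, grid$dt, MoreArgs = list(p = p))
  expect_equal(got, unname(want))
  # potentiation is non-negative, depression non-positive
  expect_true(all(got[grid$dt <= 0] >= 0))
  expect_true(all(got[grid$dt > 0] <= 0))
})

test_that("pairing windows decay with the pairing interval", {
  p <- stdp_params()
  pot <- stdp_delta(rep(2, 30), seq(0, -29), p)
  expect_true(all(diff(pot) < 0))           # decreasing in |dt| for dt <= 0
  dep <- abs(stdp_delta(rep(2, 30), seq(1, 30), p))
  expect_true(all(diff(dep) < 0))           # magnitude decreasing in dt > 0
})

test_that("default amplitudes keep the 3:1 LTP:LTD ratio and reject a zero LTD window", {
  p <- stdp_params()
  expect_equal(abs(p$a_plus) / abs(p$a_minus), 3)
  expect_error(stdp_params(tau_minus = 0), "degenerate")
})

test_that("a single pre-post pair potentiates exactly one entry", {
  p <- stdp_params(w_min = 0, w_max = 2)
  W <- matrix(1, 3, 2)
  # pre neuron 2 spiked at step 10; post neuron 1 spikes now (step 12)
  last_pre <- c(-1L, 10L, -1L)
  last_post <- c(-1L, -1L)
  W2 <- update_projection(W, last_pre, last_post,
                          spiked_pre = c(FALSE, FALSE, FALSE),
                          spiked_post = c(TRUE, FALSE), p, step = 12L)
  expect_equal(W2[2, 1], 1 + stdp_oracle(1, -2, p))
  W2[2, 1] <- 1
  expect_equal(W2, W)   # every other entry untouched
})

test_that("no spikes leave the projection unchanged", {
  p <- stdp_params()
  W <- matrix(runif(12), 4, 3)
  expect_equal(update_projection(W, rep(5L, 4), rep(7L, 3),
                                 rep(FALSE, 4), rep(FALSE, 3), p, 10L), W)
})

test_that("stepped updates equal an event-by-event replay on random rasters", {
  p <- stdp_params(w_min = 0, w_max = 3)
  set.seed(11)
  for (rep_i in 1:5) {
    n_pre <- sample(2:8, 1); n_post <- sample(2:8, 1); n_steps <- 50
    pre <- matrix(rbinom(n_steps * n_pre, 1, 0.1), n_steps, n_pre)
    post <- matrix(rbinom(n_steps * n_post, 1, 0.1), n_steps, n_post)
    W0 <- matrix(runif(n_pre * n_post, 0.5, 2.5), n_pre, n_post)
    expect_equal(stdp_apply_steps(W0, pre, post, p),
                 stdp_replay_oracle(W0, pre, post, p), tolerance = 1e-12)
  }
})

test_that("weights never leave their bounds and zero amplitudes freeze them", {
  p <- stdp_params(w_min = 0.2, w_max = 1.8)
  set.seed(3)
  W <- matrix(runif(16, 0.2, 1.8), 4, 4)
  last_pre <- rep(-1L, 4); last_post <- rep(-1L, 4)
  for (t in 0:80) {
    sp <- runif(4) < 0.3; sq <- runif(4) < 0.3
    W <- update_projection(W, last_pre, last_post, sp, sq, p, t)
    expect_true(all(W >= p$w_min - 1e-12 & W <= p$w_max + 1e-12))
    last_pre[sp] <- t; last_post[sq] <- t
  }
  p0 <- stdp_params(a_plus = 0, a_minus = 0)
  W2 <- update_projection(W, last_pre, last_post,
                          rep(TRUE, 4), rep(TRUE, 4), p0, 100L)
  expect_equal(W2, W)
})

test_that("clip_weights clamps elementwise", {
  p <- stdp_params(w_min = 0, w_max = 1)
  expect_equal(clip_weights(matrix(c(0.5, 0.2), 1), p),
               matrix(c(0.5, 0.2), 1))
  M <- matrix(c(-1, 0.3, 2, 0.9), 2, 2)
  expect_equal(clip_weights(M, p), pmin(pmax(M, 0), 1))
})
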