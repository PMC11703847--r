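test_that("stimulus expressions parse per the coding table", {
  expect_equal(parse_expression("AX+"),
               list(context = "A", sound = TRUE, shock = TRUE))
  expect_equal(parse_expression("Home"),
               list(context = "Home", sound = FALSE, shock = FALSE))
  expect_equal(parse_expression("B"),
               list(context = "B", sound = FALSE, shock = FALSE))
  expect_equal(parse_expression("CX-"),
               list(context = "C", sound = TRUE, shock = FALSE))
  expect_equal(parse_expression("A+"),
               list(context = "A", sound = FALSE, shock = TRUE))
  expect_error(parse_expression("ZX+"), "cannot parse")
  expect_error(parse_expression("AXX"), "cannot parse")
})

test_that("context codes are fixed, overlapping as configured, with a distinct Home", {
  a1 <- encode_context("A", 28, seed = 3)
  a2 <- encode_context("A", 28, seed = 3)
  expect_identical(a1, a2)
  b <- encode_context("B", 28, seed = 3)
  jac <- sum(a1 & b) / sum(a1 | b)
  expect_lt(abs(jac - 0.2), 0.1)
  home <- encode_context("Home", 28, seed = 3)
  expect_gt(sum(home), 0)
  expect_lt(sum(home), sum(a1))                 # low-activity pattern
  cc <- encode_context("C", 28, seed = 3)
  expect_equal(sum(home & (a1 | b | cc)), 0)    # Home disjoint
})

test_that("shock current decays per layer and vanishes outside the window", {
  ep <- episode_spec("AX+")
  expect_equal(shock_current(0, ep, 3000), 1e-9)
  expect_equal(shock_current(3, ep, 3000), 0.97e-9)
  expect_equal(shock_current(0, ep, 100), 0)
  expect_equal(shock_current(0, ep, 4000), 0)
  expect_equal(shock_current(150, ep, 3000), 0)   # decayed to zero, not negative
  ep2 <- episode_spec("AX+", shock_gain = 0.5)
  expect_equal(shock_current(0, ep2, 2500), 0.5e-9)
})

test_that("episodes default to 8000 steps with a 2000-step shock window", {
  ep <- episode_spec("AX+")
  expect_equal(ep$n_iterations, 8000L)
  expect_equal(ep$us_end - ep$us_start, 2000L)
  expect_equal(ep$us_current, 1e-9)
  expect_error(episode_spec("AX+", us_end = 9000), "us_end")
})

test_that("packaged protocols transcribe the published designs", {
  expect_setequal(list_protocols(),
                  c("cfc", "shock_magnitude", "sefl", "shock_stress", "ied"))
  cfc <- load_protocol("cfc")
  g1 <- cfc$groups[["1"]]
  expect_equal(vapply(g1, `[[`, 0L, "count"), c(5L, 15L, 3L))
  expect_equal(vapply(g1, `[[`, "", "expression"), c("AX+", "BX-", "AX-"))
  expect_equal(cfc$groups[["2"]][[3]]$expression, "BX-")

  sm <- load_protocol("shock_magnitude")
  expect_equal(vapply(sm$groups, function(g) g[[1]]$count, 0L),
               c("1" = 2L, "2" = 10L, "3" = 20L, "4" = 30L))

  sefl <- load_protocol("sefl")
  expect_equal(vapply(sefl$groups[["4"]], `[[`, "", "expression"),
               c("A+", "B+", "B"))
  expect_equal(vapply(sefl$groups[["4"]], `[[`, 0L, "count"), c(15L, 1L, 1L))

  ied <- load_protocol("ied")
  g1i <- ied$groups[["1"]]
  expect_equal(g1i[[1]]$gap_minutes_after, 15)   # immediate extinction
  # delayed extinction starts ~24 h after acquisition ends
  g2i <- ied$groups[["2"]]
  start_min <- g2i[[1]]$count + g2i[[1]]$gap_minutes_after +
    g2i[[2]]$count + g2i[[2]]$gap_minutes_after
  expect_equal(start_min, 1440)
})

test_that("episodes run deterministically and a silent network never freezes", {
  spec <- quiet_spec()
  net <- build_network(spec, 4)
  for (i in seq_along(net$conns)) net$conns[[i]]$W[] <- 0
  set.seed(1)
  out <- run_episode(net, "Home")
  expect_equal(out$result$freezing_percent, 0)

  net2 <- build_network(spec, 4)
  set.seed(99)
  r1 <- run_episode(net2, "AX+", plasticity = FALSE)
  set.seed(99)
  r2 <- run_episode(net2, "AX+", plasticity = FALSE)
  expect_equal(r1$result, r2$result)
  expect_identical(r1$network$regions, r2$network$regions)
})

test_that("home calibration meets its criterion or fails loudly", {
  expect_error(calibrate_home(build_network(micro_spec(), 1),
                              max_episodes = 0), "did not stabilize")
  net <- build_network(micro_spec(), 1)
  net <- calibrate_home(net)
  hist <- attr(net, "calibration")
  expect_gte(length(hist), 10)
  expect_true(all(tail(hist, 10) < 10))
  expect_true(net$calibrated)
})

test_that("groups execute their phase tables with clock gaps and stress triggers", {
  net <- build_network(micro_spec(), 5)
  net <- calibrate_home(net)
  res <- run_group("cfc", "1", seed = 5, network = net)
  expect_equal(nrow(res), 23)                      # 5 + 15 + 3
  expect_equal(res$phase, rep(c("CFC1", "CFC2", "CFC3"), c(5, 15, 3)))
  expect_equal(res$expression, rep(c("AX+", "BX-", "AX-"), c(5, 15, 3)))
  expect_true(all(res$freezing_percent >= 0 & res$freezing_percent <= 100))
  # 5 shocks never trigger stress
  expect_true(all(res$beta_ne == 0 & res$beta_cort == 0))
  expect_true(all(res$ca1_fraction == 0.10))

  # 20 shock-paired episodes cross the 15-episode stress threshold: the
  # onset lands after the 15th episode, so the 17th starts 1 min later
  sm <- run_group("shock_magnitude", "3", seed = 5, network = net)
  acq <- sm[sm$phase == "SM1", ]
  expect_true(all(acq$beta_ne[1:16] == 0))
  expect_equal(acq$beta_ne[17], beta_ne(1))
  expect_gt(acq$ca1_fraction[17], 0.10)
  # next day the hormones are back at baseline
  expect_true(all(sm$beta_ne[sm$phase == "SM2"] == 0))
})

test_that("a zero shock gain reduces every episode to a no-US run", {
  net <- build_network(micro_spec(), 6)
  net <- calibrate_home(net)
  res <- run_group("sefl", "4", seed = 6, network = net, shock_gain = 0)
  expect_true(all(res$beta_ne == 0))   # stress never triggers without US
})
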