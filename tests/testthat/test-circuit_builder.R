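test_that("the packaged circuit validates with no errors", {
  spec <- default_network_spec("full")
  v <- validate_spec(spec)
  expect_length(v$errors, 0)
  # defaulted weight means are surfaced as warnings, not errors
  expect_true(any(grepl("defaulted weight mean", v$warnings)))
})

test_that("structural defects are rejected with informative messages", {
  spec <- default_network_spec()
  spec$connections[[1]]$from <- "XYZ"
  v <- validate_spec(spec)
  expect_true(any(grepl("XYZ", v$errors)))
  expect_error(build_network(spec), "XYZ")

  spec2 <- default_network_spec()
  spec2$stdp$tau_minus <- 0
  expect_true(any(grepl("tau_minus", validate_spec(spec2)$errors)))

  spec3 <- default_network_spec()
  spec3$regions$CeM$k <- 99
  expect_true(any(grepl("exceeds layer size", validate_spec(spec3)$errors)))

  spec4 <- default_network_spec()
  spec4$connections <- c(spec4$connections, spec4$connections[1])
  expect_true(any(grepl("duplicate connection", validate_spec(spec4)$errors)))
})

test_that("weight initialization is normal, masked, non-negative and reproducible", {
  cn <- list(mu = 1.2, sd = 0, connectivity = 1)
  expect_equal(init_weights(cn, 4, 3), matrix(1.2, 4, 3))

  cn2 <- list(mu = 1.2, sd = 0.3, connectivity = 1)
  W <- init_weights(cn2, 500, 50, seed = 42)
  se <- 0.3 / sqrt(500 * 50)
  expect_lt(abs(mean(W) - 1.2), 3 * se + 1e-3)  # CLT bound (+clamp bias)
  expect_true(all(W >= 0))
  expect_equal(init_weights(cn2, 500, 50, seed = 42), W)

  cn3 <- list(mu = 1, sd = 0, connectivity = 0.5)
  W3 <- init_weights(cn3, 100, 100, seed = 1)
  expect_lt(abs(mean(W3 > 0) - 0.5), 0.05)
})

test_that("the built network matches the published architecture", {
  spec <- default_network_spec("full")
  expect_equal(spec$regions$DG$n, 500L)
  expect_equal(spec$regions$CeM$n, 2L)
  sizes <- vapply(spec$regions, function(r) r$n, numeric(1))
  expect_equal(sum(sizes), 1112)   # sum of all population sizes

  usla <- Filter(function(cn) cn$from == "US" && cn$to == "LA",
                 spec$connections)[[1]]
  expect_equal(usla$mu, 1.52)
  csla <- Filter(function(cn) cn$from == "CS" && cn$to == "LA",
                 spec$connections)[[1]]
  expect_equal(csla$mu, 0.35)

  net <- build_network(scale_network_spec(spec, 16), seed = 1)
  expect_equal(length(net$regions), 20)
  for (cn in net$conns) {
    n_src <- if (cn$from %in% names(net$spec$regions))
      net$spec$regions[[cn$from]]$n else net$spec$externals[[cn$from]]$n
    expect_equal(dim(cn$W), c(n_src, net$spec$regions[[cn$to]]$n))
    expect_true(all(cn$W >= cn$w_min & cn$W <= cn$w_max))
  }
})

test_that("the signed afferent template is a bijection with the connection list", {
  # one connection per signed synaptic-input term, no extras
  spec <- default_network_spec("full")
  key <- sort(vapply(spec$connections,
                     function(cn) paste(cn$from, cn$to, cn$sign), ""))
  expected <- sort(c(
    "Context EC_II 1", "RE EC_II 1", "EC_II EC_II -1",
    "EC_II DG 1", "DG DG -1",
    "EC_II CA3 1", "DG CA3 1", "CA3 CA3 1",
    "CA3 CA1 1", "RE CA1 1", "BA_F CA1 1", "CA1 CA1 -1",
    "CA1 EC_V 1", "EC_II EC_V 1", "EC_V EC_V -1",
    "PL IL 1", "BA_E IL 1", "US IL -1", "CA1 IL 1", "LC IL 1",
    "RE PL 1", "CA1 PL 1", "BA_F PL 1", "LC PL 1",
    "PL RE 1", "IL RE 1", "CA1 RE 1",
    "CS LA 1", "US LA 1", "LA_PV LA -1",
    "CS LA_PV 1", "LA_CCK LA_PV -1",
    "US LA_CCK 1",
    "IL BA_E 1", "BA_CCK BA_E -1",
    "LA BA_CCK 1", "BA_F BA_CCK 1",
    "LA BA_F 1", "PL BA_F 1", "CA1 BA_F 1", "BA_PV BA_F -1",
    "ITC_V BA_F -1",
    "BA_E BA_PV 1", "IL BA_PV 1",
    "LA ITC_D 1", "PL ITC_D 1",
    "BA_E ITC_V 1", "IL ITC_V 1", "ITC_D ITC_V -1",
    "LA CeL_ON 1",
    "CeL_ON CeL_OFF -1", "ITC_D CeL_OFF -1",
    "BA_F CeM 1", "ITC_V CeM -1", "CeL_OFF CeM -1"))
  expect_equal(key, expected)
})

test_that("region input implements the signed driving-force sums", {
  net <- build_network(quiet_spec(), seed = 2)
  # all afferents silent: zero current
  expect_equal(region_input(net, "CeM"), rep(0, length(net$regions$CeM$v)))

  # CeM with only CeL_OFF active is strictly non-positive
  drives <- list(CeL_OFF = rep(1, length(net$regions$CeL_OFF$v)))
  expect_true(all(region_input(net, "CeM", drives) <= 0))

  # hand-computed signed sum at rest with unit weights: with all of
  # BA_F and CeL_OFF active, the CeM current is
  #   n_BA_F * w * g_BA * (E_E - V)  -  n_CeL * w * g_CeL * (V - E_I)
  p <- net$params
  idx_ba <- which(vapply(net$conns, function(cn)
    cn$from == "BA_F" && cn$to == "CeM", logical(1)))
  idx_cel <- which(vapply(net$conns, function(cn)
    cn$from == "CeL_OFF" && cn$to == "CeM", logical(1)))
  n_ba <- length(net$regions$BA_F$v)
  n_cel <- length(net$regions$CeL_OFF$v)
  net$conns[[idx_ba]]$W[] <- 0.5
  net$conns[[idx_cel]]$W[] <- 2
  drives2 <- list(BA_F = rep(1, n_ba), CeL_OFF = rep(1, n_cel))
  got <- region_input(net, "CeM", drives2)
  g_ba <- net$conns[[idx_ba]]$gscale * p$g_leak
  g_cel <- net$conns[[idx_cel]]$gscale * p$g_leak
  want <- n_ba * 0.5 * g_ba * (p$e_exc - (-70e-3)) -
    n_cel * 2 * g_cel * ((-70e-3) - p$e_inh)
  expect_equal(got, rep(want, 2))
  expect_error(region_input(net, "Nowhere"), "unknown region")
})

test_that("builds are reproducible and distinct across seeds", {
  spec <- micro_spec()
  n1 <- build_network(spec, 7)
  n2 <- build_network(spec, 7)
  n3 <- build_network(spec, 8)
  expect_identical(lapply(n1$conns, `[[`, "W"), lapply(n2$conns, `[[`, "W"))
  expect_false(identical(lapply(n1$conns, `[[`, "W"),
                         lapply(n3$conns, `[[`, "W")))
})
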