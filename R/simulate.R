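# Episode simulation: packs a built network into the flat structures the
# compiled core consumes, runs one episode, and unpacks the results.

pack_externals <- function(network, frame, episode) {
  ext <- network$spec$externals
  ctx <- encode_context(frame$context, ext$Context$n, network$seed)
  us_gain <- if (frame$shock)
    shock_current(0, episode, episode$us_start) / 1e-9 else 0
  list(
    Context = list(activity = ctx, windowed = FALSE),
    CS = list(activity = rep(if (frame$sound) 1 else 0, ext$CS$n),
              windowed = FALSE),
    US = list(activity = rep(us_gain, ext$US$n), windowed = TRUE),
    LC = list(activity = rep(1, ext$LC$n), windowed = FALSE))
}

pack_regions <- function(network, hormone) {
  p <- network$params
  kw <- network$spec$kwta
  rn <- names(network$spec$regions)
  lapply(rn, function(r) {
    st <- network$regions[[r]]
    list(n = length(st$v), e_leak = p$e_leak, e_exc = p$e_exc,
         e_inh = p$e_inh, v_th = p$v_th, v_reset = p$v_reset,
         noise_mean = p$noise_mean, noise_sd = p$noise_sd,
         g_leak = p$g_leak,
         k = layer_sparsity(network, r, hormone),
         w_exc = network$spec$regions[[r]]$w_exc %||% kw$w_exc,
         w_inib = kw$w_inib,
         refractory_steps = p$refractory_steps,
         v = st$v, refr = st$refractory_remaining)
  })
}

pack_conns <- function(network, beta_ne_level) {
  rn <- names(network$spec$regions)
  en <- names(network$spec$externals)
  lapply(network$conns, function(cn) {
    pre_ext <- cn$from %in% en
    list(pre_ext = pre_ext,
         pre = (if (pre_ext) match(cn$from, en) else match(cn$from, rn)) - 1L,
         post = match(cn$to, rn) - 1L,
         sign = cn$sign, gscale = cn$gscale,
         gain = if (cn$modulated) 1 + beta_ne_level else 1,
         plastic = cn$plastic, w_min = cn$w_min, w_max = cn$w_max,
         W = cn$W)
  })
}

#' Run one behavioral episode
#'
#' Simulates `n_iterations` steps of the full loop (external drives,
#' signed region inputs with k-WTA and neuromodulation, membrane
#' integration, spiking, STDP on plastic projections), converts
#' medial-central-amygdala activity to a freezing percentage, advances the
#' behavioral clock and applies the stress-trigger rule for shock-paired
#' episodes.
#'
#' @param network a [build_network()] object.
#' @param episode an [episode_spec()] (or an expression string).
#' @param hormone a [hormone_state()]; `NULL` runs without stress.
#' @param plasticity logical; `FALSE` freezes all weights.
#' @return A list with the updated `network`, `hormone`, and a one-row
#'   tibble `result` (freezing percentage, CeM spike count, hormone
#'   snapshot, per-region spike totals as a list column).
#' @export
run_episode <- function(network, episode, hormone = NULL,
                        plasticity = TRUE) {
  if (is.character(episode)) episode <- episode_spec(episode)
  frame <- parse_expression(episode$expression)
  lev <- hormone_levels(hormone)
  rn <- names(network$spec$regions)
  regions <- pack_regions(network, hormone)
  conns <- pack_conns(network, lev$beta_ne)
  if (!plasticity) for (i in seq_along(conns)) conns[[i]]$plastic <- FALSE
  exts <- pack_externals(network, frame, episode)
  cpp_seed <- sample.int(2147483646L, 1)
  out <- run_episode_core(regions, conns, exts,
                          episode$n_iterations,
                          if (frame$shock && episode$shock_gain > 0)
                            episode$us_start else 0L,
                          if (frame$shock && episode$shock_gain > 0)
                            episode$us_end else 0L,
                          network$spec$stdp_params %||% list(
                            a_plus = network$spec$stdp$a_plus,
                            a_minus = network$spec$stdp$a_minus,
                            tau_w = network$spec$stdp$tau_w,
                            tau_plus = network$spec$stdp$tau_plus,
                            tau_minus = network$spec$stdp$tau_minus),
                          match("CeM", rn) - 1L, cpp_seed,
                          exp(-1 / network$spec$tau_syn))
  for (i in seq_along(network$conns)) {
    if (!is.null(out$weights[[i]])) network$conns[[i]]$W <- out$weights[[i]]
  }
  for (i in seq_along(rn)) {
    network$regions[[rn[i]]]$v <- out$v[[i]]
    network$regions[[rn[i]]]$refractory_remaining <- out$refr[[i]]
  }
  freezing <- freezing_percent(out$readout_counts)
  if (!is.null(hormone)) {
    hormone <- advance_clock(hormone, hormone$minutes_per_episode)
    if (frame$shock && episode$shock_gain > 0)
      hormone <- stress_trigger(hormone)
  }
  result <- tibble::tibble(
    expression = episode$expression,
    freezing_percent = freezing,
    cem_spike_count = sum(out$readout_counts),
    beta_ne = lev$beta_ne, beta_cort = lev$beta_cort,
    ca1_fraction = lev$ca1_fraction,
    spike_totals = list(setNames(as.integer(out$spike_totals), rn)))
  list(network = network, hormone = hormone, result = result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Home-environment baseline calibration
#'
#' Runs Home-context episodes with plasticity on until the
#' medial-central-amygdala freezing output stays below `threshold`
#' percent for `consecutive` episodes; the resulting weight state is the
#' baseline for all groups of an experiment.
#'
#' @param network a freshly built network.
#' @param hormone optional [hormone_state()] (stress is never triggered in
#'   Home).
#' @param threshold freezing criterion (%).
#' @param consecutive episodes that must satisfy the criterion in a row.
#' @param max_episodes calibration budget; exceeded = error.
#' @return The calibrated network; the per-episode freezing history is
#'   attached as `attr(net, "calibration")`.
#' @export
calibrate_home <- function(network, hormone = NULL, threshold = 10,
                           consecutive = 10, max_episodes = 200) {
  history <- numeric(0)
  streak <- 0
  ep <- episode_spec("Home")
  while (length(history) < max_episodes) {
    step <- run_episode(network, ep, hormone)
    network <- step$network
    hormone <- step$hormone
    f <- step$result$freezing_percent
    history <- c(history, f)
    streak <- if (f < threshold) streak + 1 else 0
    if (streak >= consecutive) {
      network$calibrated <- TRUE
      attr(network, "calibration") <- history
      return(network)
    }
  }
  stop("home calibration did not stabilize below ", threshold,
       "% for ", consecutive, " consecutive episodes within ",
       max_episodes, " episodes; freezing trace: ",
       paste(round(tail(history, 20), 1), collapse = ", "))
}

#' Run one protocol group
#'
#' Builds and Home-calibrates a fresh network (unless a calibrated one is
#' supplied), then executes the group's phases in order, inserting the
#' configured behavioral-clock gaps between phases.
#'
#' @param protocol a [load_protocol()] object or protocol name.
#' @param group_id group identifier (e.g. `"1"`).
#' @param seed integer seed (network build + episode noise).
#' @param spec network spec used when building; default quarter-scale.
#' @param network optional pre-calibrated network (it is copied, not
#'   mutated).
#' @param stress enable the stress-hormone system.
#' @param shock_gain shock intensity multiplier (0 = no-US null control).
#' @return A tibble with one row per episode: group, phase, episode index,
#'   expression, freezing, CeM spikes and hormone snapshot.
#' @export
run_group <- function(protocol, group_id, seed = 1L,
                      spec = default_network_spec(), network = NULL,
                      stress = TRUE, shock_gain = 1) {
  if (is.character(protocol)) protocol <- load_protocol(protocol)
  phases <- protocol$groups[[as.character(group_id)]]
  if (is.null(phases)) stop("unknown group: ", group_id)
  set.seed(seed)
  if (is.null(network)) {
    network <- build_network(spec, seed)
    network <- calibrate_home(network)
  }
  hormone <- hormone_state(stress_enabled = stress)
  rows <- list()
  for (ph in phases) {
    for (i in seq_len(ph$count)) {
      ep <- episode_spec(ph$expression, shock_gain = shock_gain)
      stepped <- run_episode(network, ep, hormone)
      network <- stepped$network
      hormone <- stepped$hormone
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(protocol = protocol$name,
                       group = as.character(group_id),
                       phase = ph$label, episode = i),
        stepped$result)
    }
    hormone <- advance_clock(hormone, ph$gap_minutes_after)
  }
  dplyr::bind_rows(rows)
}

#' Pure-R reference episode loop
#'
#' A slow, dependency-free re-implementation of the compiled episode core
#' built from the module-level operations ([update_projection()],
#' [select_winners()] etc.), used to cross-validate the compiled loop on
#' micro-networks with zero membrane noise.
#'
#' @inheritParams run_episode
#' @param n_iter number of steps.
#' @return List with final `v`, `refr`, plastic `weights`, and per-step
#'   readout spike counts.
#' @keywords internal
#' @export
run_episode_r <- function(network, episode, hormone = NULL, n_iter = 50L) {
  if (is.character(episode)) episode <- episode_spec(episode)
  frame <- parse_expression(episode$expression)
  lev <- hormone_levels(hormone)
  p <- network$params
  kw <- network$spec$kwta
  rn <- names(network$spec$regions)
  en <- names(network$spec$externals)
  exts <- pack_externals(network, frame, episode)
  stp <- stdp_params(a_plus = network$spec$stdp$a_plus,
                     a_minus = network$spec$stdp$a_minus,
                     tau_w = network$spec$stdp$tau_w,
                     tau_plus = network$spec$stdp$tau_plus,
                     tau_minus = network$spec$stdp$tau_minus)
  decay <- exp(-1 / network$spec$tau_syn)
  reg <- lapply(rn, function(r) {
    st <- network$regions[[r]]
    list(v = st$v, refr = st$refractory_remaining,
         last = rep(-1L, length(st$v)),
         spiked = rep(FALSE, length(st$v)),
         trace = rep(0, length(st$v)),
         k = layer_sparsity(network, r, hormone))
  })
  inc <- vapply(network$conns, function(cn)
    !(cn$from %in% en) && !cn$plastic, logical(1))
  gacc <- lapply(network$conns, function(cn) rep(0, ncol(cn$W)))
  names(reg) <- rn
  W <- lapply(network$conns, function(cn) cn$W)
  readout <- integer(n_iter)
  for (t in seq_len(n_iter) - 1L) {
    in_window <- frame$shock && episode$shock_gain > 0 &&
      t >= episode$us_start && t < episode$us_end
    for (r in rn) {
      R <- reg[[r]]
      n <- length(R$v)
      gexc <- numeric(n); ginh <- numeric(n)
      for (ci in seq_along(network$conns)) {
        cn <- network$conns[[ci]]
        if (cn$to != r) next
        gain <- if (cn$modulated) 1 + lev$beta_ne else 1
        if (cn$from %in% en) {
          X <- exts[[cn$from]]
          if (X$windowed && !in_window) next
          act <- X$activity
          contrib <- numeric(n)
          for (i in which(act > 0))
            contrib <- contrib + act[i] * cn$gscale * gain * W[[ci]][i, ]
        } else if (inc[ci]) {
          contrib <- cn$gscale * gain * gacc[[ci]]
        } else {
          tr <- reg[[cn$from]]$trace
          contrib <- numeric(n)
          for (i in which(tr > 1e-4))
            contrib <- contrib + tr[i] * cn$gscale * gain * W[[ci]][i, ]
        }
        if (cn$sign > 0) gexc <- gexc + contrib else ginh <- ginh + contrib
      }
      drive <- gexc * (p$e_exc - R$v) + ginh * (p$e_inh - R$v)
      if (R$k > 0 && R$k < n) {
        winners <- select_winners(drive, R$k)
        loser <- setdiff(seq_len(n), winners)
        wexc_r <- network$spec$regions[[r]]$w_exc %||% kw$w_exc
        gexc[winners] <- gexc[winners] * wexc_r
        gexc[loser] <- 0
      }
      free <- R$refr <= 0L
      a <- 1 + gexc + ginh
      vstar <- (p$e_leak + gexc * p$e_exc + ginh * p$e_inh) / a
      vnew <- vstar + (R$v - vstar) * exp(-a)
      R$v[free] <- vnew[free]
      R$v[!free] <- p$v_reset
      R$refr[!free] <- R$refr[!free] - 1L
      fired <- R$refr == 0L & R$v > p$v_th
      R$spiked <- fired
      R$v[fired] <- p$v_reset
      R$refr[fired] <- p$refractory_steps
      reg[[r]] <- R
    }
    readout[t + 1L] <- sum(reg$CeM$spiked)
    for (ci in seq_along(network$conns)) {
      cn <- network$conns[[ci]]
      if (!cn$plastic) next
      Q <- reg[[cn$to]]
      sp <- stp; sp$w_min <- cn$w_min; sp$w_max <- cn$w_max
      if (cn$from %in% en) {
        X <- exts[[cn$from]]
        act_now <- !(X$windowed && !in_window)
        spre <- act_now & X$activity > 0
        plast <- rep(-1L, length(X$activity))
        W[[ci]] <- update_projection(W[[ci]], plast, Q$last,
                                     spre, Q$spiked, sp, t)
      } else {
        P <- reg[[cn$from]]
        W[[ci]] <- update_projection(W[[ci]], P$last, Q$last,
                                     P$spiked, Q$spiked, sp, t)
      }
    }
    for (r in rn) {
      reg[[r]]$last[reg[[r]]$spiked] <- t
      reg[[r]]$trace <- reg[[r]]$trace * decay + as.numeric(reg[[r]]$spiked)
    }
    for (ci in which(inc)) {
      g <- gacc[[ci]] * decay
      for (i in which(reg[[network$conns[[ci]]$from]]$spiked))
        g <- g + W[[ci]][i, ]
      gacc[[ci]] <- g
    }
  }
  list(v = lapply(reg, function(R) R$v),
       refr = lapply(reg, function(R) R$refr),
       weights = W, readout_counts = readout)
}
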