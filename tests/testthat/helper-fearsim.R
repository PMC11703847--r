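# Shared fixtures: micro-scale networks for fast structural tests, an
# independent STDP oracle, and a lazily computed behavioral battery.

micro_spec <- function() {
  # sixteenth-scale circuit: every population shrunk to a handful of
  # neurons (fan-in compensated), fast enough for bookkeeping tests
  scale_network_spec(default_network_spec("full"), 16)
}

quiet_spec <- function() {
  # micro spec with zero membrane noise, for deterministic traces
  sp <- micro_spec()
  sp$neuron_defaults$noise_sd <- 0
  sp
}

# independent evaluation of the pair-based soft-bound STDP rule, written
# directly from its closed form (not via stdp_delta)
stdp_oracle <- function(w, dt, p) {
  if (dt <= 0) (p$w_max - w) * p$a_plus * exp(dt / p$tau_plus) / p$tau_w
  else (p$w_min - w) * abs(p$a_minus) * exp(-dt / p$tau_minus) / p$tau_w
}

# event-by-event replay of nearest-neighbour STDP on a spike raster:
# rasters are n_steps x n matrices of 0/1
stdp_replay_oracle <- function(W0, pre_raster, post_raster, p) {
  W <- W0
  n_pre <- ncol(pre_raster); n_post <- ncol(post_raster)
  last_pre <- rep(-1L, n_pre); last_post <- rep(-1L, n_post)
  for (t in seq_len(nrow(pre_raster)) - 1L) {
    sp <- pre_raster[t + 1L, ] > 0
    sq <- post_raster[t + 1L, ] > 0
    for (j in which(sq)) {
      for (i in seq_len(n_pre)) {
        tp <- if (sp[i]) t else last_pre[i]
        if (tp < 0) next
        W[i, j] <- W[i, j] + stdp_oracle(W[i, j], tp - t, p)
      }
    }
    for (i in which(sp)) {
      for (j in seq_len(n_post)) {
        if (sq[j] || last_post[j] < 0) next
        W[i, j] <- W[i, j] + stdp_oracle(W[i, j], t - last_post[j], p)
      }
    }
    last_pre[sp] <- t
    last_post[sq] <- t
  }
  pmin(pmax(W, p$w_min), p$w_max)
}

# the same raster driven through update_projection, one call per step
stdp_apply_steps <- function(W0, pre_raster, post_raster, p) {
  W <- W0
  n_pre <- ncol(pre_raster); n_post <- ncol(post_raster)
  last_pre <- rep(-1L, n_pre); last_post <- rep(-1L, n_post)
  for (t in seq_len(nrow(pre_raster)) - 1L) {
    sp <- pre_raster[t + 1L, ] > 0
    sq <- post_raster[t + 1L, ] > 0
    W <- update_projection(W, last_pre, last_post, sp, sq, p, step = t)
    last_pre[sp] <- t
    last_post[sq] <- t
  }
  W
}

# behavioral battery shared by the acceptance tests; computed once per
# test run
.fearsim_test_cache <- new.env(parent = emptyenv())

# the groups the ordering comparisons reference
battery_groups <- list(cfc = c("1", "2"), shock_magnitude = as.character(1:4),
                       sefl = c("1", "2", "4"), shock_stress = c("1", "2", "4"),
                       ied = c("1", "2"))

get_battery <- function() {
  if (is.null(.fearsim_test_cache$battery)) {
    .fearsim_test_cache$battery <-
      run_battery(n_replicates = 15, master_seed = 1,
                  groups = battery_groups)
  }
  .fearsim_test_cache$battery
}

get_null_battery <- function() {
  if (is.null(.fearsim_test_cache$null)) {
    .fearsim_test_cache$null <-
      run_battery(n_replicates = 3, master_seed = 2, shock_gain = 0)
  }
  .fearsim_test_cache$null
}

phase_median <- function(bat, prot, grp, ph, episodes = NULL) {
  x <- bat[bat$protocol == prot & bat$group == grp & bat$phase == ph, ]
  if (!is.null(episodes)) x <- x[x$episode %in% episodes, ]
  stats::median(x$freezing_percent)
}
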