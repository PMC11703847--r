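EXTERNAL_INPUTS <- c("Context", "CS", "US", "LC")

#' Load a declarative network specification
#'
#' Reads a YAML network description (regions with sizes and sparsity
#' rules; signed, optionally plastic connections with weight-init means)
#' and converts config units (mV, ms, pF, nS) to SI.
#'
#' @param path YAML file path.
#' @return A `fearsim_network_spec` list.
#' @export
load_network_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  nd <- raw$neuron_defaults
  defaults <- neuron_params(
    c_m = nd$c_m_pf * 1e-12, g_leak = nd$g_leak_ns * 1e-9,
    e_leak = nd$e_leak_mv * 1e-3, e_exc = nd$e_exc_mv * 1e-3,
    e_inh = nd$e_inh_mv * 1e-3, v_th = nd$v_th_mv * 1e-3,
    v_reset = nd$v_reset_mv * 1e-3, v_peak = nd$v_peak_mv * 1e-3,
    tau = nd$tau_ms * 1e-3, noise_mean = nd$noise_mean_mv * 1e-3,
    noise_sd = nd$noise_sd_mv * 1e-3,
    refractory_steps = nd$refractory_steps)
  st <- raw$stdp
  conns <- lapply(raw$connections, function(cn) {
    list(from = cn$from, to = cn$to, sign = as.integer(cn$sign),
         mu = cn$mu, sd = if (is.null(cn$sd)) 0.3 else cn$sd,
         plastic = isTRUE(cn$plastic),
         connectivity = if (is.null(cn$connectivity)) 1 else cn$connectivity,
         modulated = isTRUE(cn$modulated),
         gmult = if (is.null(cn$gmult)) 1 else cn$gmult,
         w_max_scale = cn$w_max_scale,
         default_mu = isTRUE(cn$default_mu))
  })
  spec <- structure(list(
    name = raw$name,
    g_total = raw$g_total,
    tau_syn = if (is.null(nd$tau_syn_steps)) 2 else nd$tau_syn_steps,
    ext_gain = if (is.null(raw$ext_gain)) 1 else raw$ext_gain,
    inh_gain = if (is.null(raw$inh_gain)) 1 else raw$inh_gain,
    neuron_defaults = defaults,
    stdp = list(a_plus = st$a_plus, a_minus = st$a_minus,
                tau_w = st$tau_w, tau_plus = st$tau_plus,
                tau_minus = st$tau_minus, w_min = st$w_min,
                w_max_scale = st$w_max_scale),
    kwta = list(w_exc = raw$kwta$w_exc, w_inib = raw$kwta$w_inib),
    externals = lapply(raw$externals, function(x)
      list(n = x$size, active = x$active)),
    regions = lapply(raw$regions, function(x) {
      list(n = x$size, n_ref = x$size,
           sparsity_fraction = x$sparsity_fraction, k = x$k,
           w_exc = x$w_exc)
    }),
    connections = conns,
    scale = 1), class = "fearsim_network_spec")
  spec
}

#' The packaged default fear/stress circuit
#'
#' Region sizes, signed connections and weight means of the full published
#' architecture (20 populations from entorhinal cortex to the medial
#' central amygdala, plus the four stimulus channels). `scale = "quarter"`
#' divides region sizes by four (minimum 2 neurons) and compensates
#' internal synaptic conductances by the size ratio so that mean afferent
#' drive is preserved; it is the default for tests and desk-scale runs.
#'
#' @param scale `"quarter"` or `"full"`.
#' @return A `fearsim_network_spec`.
#' @export
#' @examples
#' spec <- default_network_spec()
#' spec$regions$DG$n
default_network_spec <- function(scale = c("quarter", "full")) {
  scale <- match.arg(scale)
  spec <- load_network_spec(
    system.file("extdata", "network_default.yaml", package = "fearsim"))
  if (scale == "quarter") spec <- scale_network_spec(spec, 4)
  spec
}

#' Scale region sizes down with fan-in compensation
#'
#' @param spec a `fearsim_network_spec`.
#' @param factor size divisor (> 1 shrinks the network).
#' @return The scaled spec; `n_ref` keeps the reference size so internal
#'   conductances are multiplied by `n_ref/n` at build time.
#' @export
scale_network_spec <- function(spec, factor) {
  stopifnot(factor >= 1)
  spec$regions <- lapply(spec$regions, function(r) {
    r$n <- max(2L, as.integer(round(r$n_ref / factor)))
    r
  })
  spec$scale <- factor
  spec
}

#' Validate a network specification
#'
#' Checks structural consistency: declared regions unique and non-empty,
#' connection endpoints declared (regions or the external inputs Context /
#' CS / US / LC), non-negative weight means, valid signs, no duplicate
#' projections, a positive LTD time constant, and k-WTA counts within the
#' layer size. Fatal findings are errors (the build refuses the spec);
#' defaulted weight means are reported as warnings.
#'
#' @param spec a `fearsim_network_spec`.
#' @return A list with character vectors `errors` and `warnings`.
#' @export
validate_spec <- function(spec) {
  errors <- character(0); warnings <- character(0)
  rn <- names(spec$regions)
  if (anyDuplicated(rn)) errors <- c(errors, "duplicate region names")
  for (r in rn) {
    if (spec$regions[[r]]$n < 1)
      errors <- c(errors, paste0("region ", r, " has no neurons"))
    k <- spec$regions[[r]]$k
    if (!is.null(k) && k > spec$regions[[r]]$n)
      errors <- c(errors, paste0("region ", r, ": k (", k,
                                 ") exceeds layer size"))
  }
  valid_ends <- c(rn, names(spec$externals), EXTERNAL_INPUTS)
  seen <- character(0)
  for (cn in spec$connections) {
    if (!(cn$from %in% valid_ends))
      errors <- c(errors, paste0("connection from undeclared region \"",
                                 cn$from, "\""))
    if (!(cn$to %in% rn))
      errors <- c(errors, paste0("connection to undeclared region \"",
                                 cn$to, "\""))
    if (cn$mu < 0)
      errors <- c(errors, paste0("negative weight mean on ", cn$from,
                                 " -> ", cn$to))
    if (!(cn$sign %in% c(-1L, 1L)))
      errors <- c(errors, paste0("invalid sign on ", cn$from, " -> ", cn$to))
    key <- paste(cn$from, cn$to)
    if (key %in% seen)
      errors <- c(errors, paste0("duplicate connection ", cn$from, " -> ",
                                 cn$to))
    seen <- c(seen, key)
    if (cn$default_mu)
      warnings <- c(warnings, paste0("defaulted weight mean (1.0) on ",
                                     cn$from, " -> ", cn$to))
  }
  if (spec$stdp$tau_minus <= 0)
    errors <- c(errors,
                "stdp tau_minus must be > 0 (a zero LTD window is degenerate)")
  list(errors = errors, warnings = warnings)
}

#' Initialize one projection's weight matrix
#'
#' Weights are drawn from `N(mu, sd)` and clamped at zero (magnitudes;
#' signs live in the connection spec, not the weights), then masked by the
#' connectivity fraction. Deterministic given the R RNG state (or `seed`).
#'
#' @param conn a connection spec entry (list with `mu`, `sd`,
#'   `connectivity`).
#' @param n_src,n_tgt source / target population sizes.
#' @param seed optional local seed.
#' @return `n_src x n_tgt` non-negative weight matrix.
#' @export
init_weights <- function(conn, n_src, n_tgt, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(pmax(0, rnorm(n_src * n_tgt, conn$mu, conn$sd)), n_src, n_tgt)
  if (conn$connectivity < 1) {
    mask <- matrix(runif(n_src * n_tgt) < conn$connectivity, n_src, n_tgt)
    w <- w * mask
  }
  w
}

#' Build a runtime network from a specification
#'
#' Validates the spec, instantiates every population at rest and draws all
#' weight matrices with the given seed. Identical (spec, seed) pairs yield
#' identical networks.
#'
#' @param spec a `fearsim_network_spec`.
#' @param seed integer RNG seed for weight initialization.
#' @return A `fearsim_network` object.
#' @export
#' @examples
#' net <- build_network(default_network_spec(), seed = 1)
#' nrow(net$conns[[1]]$W)
build_network <- function(spec, seed = 1L) {
  v <- validate_spec(spec)
  if (length(v$errors) > 0)
    stop("invalid network spec:\n  ", paste(v$errors, collapse = "\n  "))
  set.seed(seed)
  params <- spec$neuron_defaults
  regions <- lapply(spec$regions, function(r) {
    s <- layer_state(r$n, params)
    s
  })
  pop_size <- function(name) {
    if (name %in% names(spec$regions)) spec$regions[[name]]$n
    else spec$externals[[name]]$n
  }
  # typical active pool of a source population: its k-WTA winner count
  # for sparse layers, its designed active-unit count for stimulus
  # channels, its size otherwise
  n_eff <- function(name) {
    if (name %in% names(spec$regions)) {
      r <- spec$regions[[name]]
      if (!is.null(r$k)) return(r$k)
      if (!is.null(r$sparsity_fraction))
        return(max(1, round(r$sparsity_fraction * r$n)))
      return(r$n)
    }
    spec$externals[[name]]$active
  }
  conns <- lapply(spec$connections, function(cn) {
    n_src <- pop_size(cn$from); n_tgt <- pop_size(cn$to)
    w_max <- (cn$w_max_scale %||% spec$stdp$w_max_scale) * max(cn$mu, 0.1)
    W <- pmin(init_weights(cn, n_src, n_tgt), w_max)
    ext <- !(cn$from %in% names(spec$regions))
    list(from = cn$from, to = cn$to, sign = cn$sign, W = W,
         plastic = cn$plastic, modulated = cn$modulated,
         w_min = spec$stdp$w_min,
         w_max = w_max,
         gscale = spec$g_total / n_eff(cn$from) * cn$gmult *
           (if (ext) spec$ext_gain else 1) *
           (if (cn$sign < 0) spec$inh_gain else 1))
  })
  structure(list(spec = spec, params = params, regions = regions,
                 conns = conns, seed = seed,
                 calibrated = FALSE),
            class = "fearsim_network")
}

#' Signed synaptic input to one region
#'
#' Reference implementation of the per-region signed weighted sum: each
#' afferent projection contributes its conductance (presynaptic activity
#' times weights, scaled to siemens) through the driving force toward the
#' excitatory or inhibitory reversal potential. Prefrontal populations
#' (PL, IL) route their locus-coeruleus term through the hormonal gain
#' `(1 + beta_NE)`.
#'
#' Used for unit-level verification and micro-network traces; episode
#' simulation runs the identical computation in compiled code.
#'
#' @param network a [build_network()] object.
#' @param region target region name.
#' @param drives named list of presynaptic activity: logical/0-1 spike
#'   vectors for internal regions, activity vectors for external channels
#'   (`Context`, `CS`, `US`, `LC`). Missing entries count as silent.
#' @param hormone a [hormone_state()] or `NULL`.
#' @return Current vector (A), one entry per neuron of `region`.
#' @export
region_input <- function(network, region, drives = list(), hormone = NULL) {
  if (!(region %in% names(network$spec$regions)))
    stop("unknown region: ", region)
  st <- network$regions[[region]]
  v <- st$v
  p <- network$params
  lev <- hormone_levels(hormone)
  i_total <- rep(0, length(v))
  i_inf <- rep(0, length(v))
  for (cn in network$conns) {
    if (cn$to != region) next
    act <- drives[[cn$from]]
    if (is.null(act)) next
    act <- as.numeric(act)
    if (length(act) != nrow(cn$W))
      stop("activity length mismatch for ", cn$from)
    g <- as.numeric(act %*% cn$W) * cn$gscale * p$g_leak
    e_syn <- if (cn$sign > 0) p$e_exc else p$e_inh
    contrib <- synaptic_drive(g, v, e_syn)
    if (cn$modulated) i_inf <- i_inf + contrib
    else i_total <- i_total + contrib
  }
  i_total + modulated_input(i_inf, lev$beta_ne)
}
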