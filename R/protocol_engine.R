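#' Parse a stimulus expression
#'
#' Stimulus expressions name the context (`Home`, `A`, `B`, `C`), an
#' optional tone (`X`) and an optional shock marker (`+` = shock, `-` = no
#' shock): `"AX+"` is context A with tone and shock, `"B"` is context B
#' alone, `"A+"` is a context-shock pairing without the tone.
#'
#' @param expr expression string.
#' @return A list with `context`, `sound` (logical) and `shock` (logical).
#' @export
#' @examples
#' parse_expression("AX+")
parse_expression <- function(expr) {
  if (identical(expr, "Home"))
    return(list(context = "Home", sound = FALSE, shock = FALSE))
  m <- regmatches(expr, regexec("^([ABC])(X?)([+-]?)$", expr))[[1]]
  if (length(m) == 0)
    stop("cannot parse stimulus expression \"", expr,
         "\": expected Home or [ABC][X][+-]")
  list(context = m[2], sound = nzchar(m[3]), shock = identical(m[4], "+"))
}

#' Deterministic binary context patterns
#'
#' Encodes the four contexts as fixed binary activity patterns over the
#' context input units. A, B and C are equally active (35% of units by
#' default) with a configurable pairwise Jaccard overlap; Home is a
#' distinct low-activity pattern (20% of units, disjoint from A/B/C).
#' Patterns depend only on `(context_id, seed)`.
#'
#' @param context_id one of `"Home"`, `"A"`, `"B"`, `"C"`.
#' @param n_units number of context input units (>= 4).
#' @param seed integer seed fixing the patterns.
#' @param active_fraction fraction of units active in A/B/C.
#' @param overlap target pairwise Jaccard overlap between A, B and C.
#' @param home_fraction fraction of units active in Home.
#' @return 0/1 numeric vector of length `n_units`.
#' @export
encode_context <- function(context_id, n_units, seed,
                           active_fraction = 0.35, overlap = 0.2,
                           home_fraction = 0.2) {
  stopifnot(n_units >= 4)
  if (!context_id %in% c("Home", "A", "B", "C"))
    stop("unknown context: ", context_id)
  pats <- context_pattern_set(n_units, seed, active_fraction, overlap,
                              home_fraction)
  pats[[context_id]]
}

context_pattern_set <- function(n_units, seed, active_fraction = 0.35,
                                overlap = 0.2, home_fraction = 0.2) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n_act <- max(2L, round(active_fraction * n_units))
  n_shared <- max(1L, round(2 * n_act * overlap / (1 + overlap)))
  n_shared <- min(n_shared, n_act - 1L)
  units <- seq_len(n_units)
  A <- sample(units, n_act)
  B <- c(sample(A, n_shared), sample(setdiff(units, A), n_act - n_shared))
  onlyA <- setdiff(A, B); onlyB <- setdiff(B, A)
  fresh <- setdiff(units, union(A, B))
  n_fresh <- max(0L, n_act - 2L * n_shared)
  C <- c(sample(onlyA, min(n_shared, length(onlyA))),
         sample(onlyB, min(n_shared, length(onlyB))),
         sample(fresh, min(n_fresh, length(fresh))))
  n_home <- max(1L, round(home_fraction * n_units))
  free <- setdiff(units, Reduce(union, list(A, B, C)))
  home <- if (length(free) >= n_home) sample(free, n_home)
          else c(free, sample(setdiff(units, free), n_home - length(free)))
  as_pat <- function(idx) { p <- numeric(n_units); p[idx] <- 1; p }
  list(Home = as_pat(home), A = as_pat(A), B = as_pat(B), C = as_pat(C))
}

#' Episode specification
#'
#' One behavioral episode: 8,000 integration steps (4,000 ms at a 0.5 ms
#' step), with the shock delivered during a contiguous 2,000-step window
#' when the expression carries a `+`. The sensory shock current is
#' 1.00 nA, decaying by 0.01 nA per synaptic layer of depth.
#'
#' @param expression stimulus expression (see [parse_expression()]).
#' @param n_iterations steps per episode.
#' @param us_start,us_end shock window, 0-based step range `[start, end)`.
#' @param us_current sensory shock current (A).
#' @param layer_decay current decay per synaptic layer (A).
#' @param shock_gain dimensionless intensity multiplier.
#' @return A `fearsim_episode_spec` list.
#' @export
episode_spec <- function(expression, n_iterations = 8000L,
                         us_start = 2000L, us_end = 4000L,
                         us_current = 1e-9, layer_decay = 0.01e-9,
                         shock_gain = 1) {
  stopifnot(us_start >= 0, us_end <= n_iterations, us_start <= us_end,
            us_current >= 0, shock_gain >= 0)
  parse_expression(expression)  # validates
  structure(list(expression = expression,
                 n_iterations = as.integer(n_iterations),
                 us_start = as.integer(us_start),
                 us_end = as.integer(us_end),
                 us_current = us_current, layer_decay = layer_decay,
                 shock_gain = shock_gain),
            class = "fearsim_episode_spec")
}

#' Shock current at a given circuit depth
#'
#' Inside the shock window the sensory current is
#' `max(0, us_current - layer_decay * layer_depth) * shock_gain`;
#' zero outside the window.
#'
#' @param layer_depth synaptic layers from the stimulated sensory layer
#'   (depth 0).
#' @param episode an [episode_spec()].
#' @param iteration 0-based step index.
#' @return Current (A).
#' @export
#' @examples
#' shock_current(0, episode_spec("AX+"), 3000)  # 1 nA
#' shock_current(3, episode_spec("AX+"), 3000)  # 0.97 nA
shock_current <- function(layer_depth, episode, iteration) {
  stopifnot(layer_depth >= 0)
  inside <- iteration >= episode$us_start & iteration < episode$us_end
  ifelse(inside,
         pmax(0, episode$us_current - episode$layer_decay * layer_depth) *
           episode$shock_gain,
         0)
}

#' Load a packaged behavioral protocol
#'
#' The five shipped protocols transcribe the published experimental
#' designs: `cfc` (contextual fear conditioning with renewal),
#' `shock_magnitude` (2/10/20/30 shocks), `sefl` (stress-enhanced fear
#' learning), `shock_stress` (shock-stress ordering) and `ied`
#' (immediate extinction deficit).
#'
#' @param name protocol name or a YAML file path.
#' @return A `fearsim_protocol` list: `name` plus `groups`, each an
#'   ordered list of phases `(label, count, expression,
#'   gap_minutes_after)`.
#' @export
#' @examples
#' p <- load_protocol("cfc")
#' names(p$groups)
load_protocol <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "protocols", paste0(name, ".yaml"),
                package = "fearsim")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown protocol: ", name)
  raw <- yaml::read_yaml(path)
  groups <- lapply(raw$groups, function(phases) {
    lapply(phases, function(ph) {
      parse_expression(ph$expression)  # validates
      list(label = ph$label, count = as.integer(ph$count),
           expression = ph$expression,
           gap_minutes_after = if (is.null(ph$gap_minutes_after)) 0
                               else ph$gap_minutes_after)
    })
  })
  structure(list(name = raw$name, groups = groups),
            class = "fearsim_protocol")
}

#' Names of the packaged protocols
#' @return Character vector of protocol names.
#' @export
list_protocols <- function() {
  dir <- system.file("extdata", "protocols", package = "fearsim")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}
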