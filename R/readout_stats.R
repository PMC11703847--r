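#' Freezing percentage from a CeM spike raster
#'
#' Freezing is read out from medial-central-amygdala (CeM) activity on the
#' theta time scale: the episode is cut into non-overlapping windows of
#' `window_length` steps (250 steps = 125 ms, one 8 Hz theta cycle) and
#' the freezing percentage is the share of windows containing at least
#' one CeM spike.
#'
#' @param cem_spike_raster per-step CeM spike counts (or logical flags)
#'   covering a whole episode.
#' @param window_length steps per theta window.
#' @return Freezing percentage in `[0, 100]`.
#' @export
#' @examples
#' freezing_percent(rep(0, 1000), 250)  # 0
freezing_percent <- function(cem_spike_raster, window_length = 250L) {
  n <- length(cem_spike_raster)
  if (n < window_length)
    stop("raster shorter than one window (", n, " < ", window_length, ")")
  n_win <- n %/% window_length
  x <- cem_spike_raster[seq_len(n_win * window_length)]
  active <- tapply(x, rep(seq_len(n_win), each = window_length),
                   function(w) any(w > 0))
  100 * sum(active) / n_win
}

#' Replicate battery for a protocol
#'
#' Runs `n_replicates` independent full simulations of a protocol: for
#' each replicate a fresh network is built and Home-calibrated with a
#' derived seed, and the calibrated weight state is the shared baseline
#' for every group of the experiment. Returns one row per episode.
#'
#' @param protocol protocol name or [load_protocol()] object.
#' @param groups group ids to run (default: all groups of the protocol).
#' @param n_replicates number of replicates.
#' @param master_seed integer; replicate seeds are derived from it.
#' @param spec network spec (default quarter-scale).
#' @param stress enable the stress-hormone system.
#' @param shock_gain shock intensity multiplier (0 = null control).
#' @return A `fearsim_replicates` tibble: replicate, seed, group, phase,
#'   episode, expression, freezing and hormone snapshots.
#' @export
run_replicates <- function(protocol, groups = NULL, n_replicates = 15L,
                           master_seed = 1L,
                           spec = default_network_spec(),
                           stress = TRUE, shock_gain = 1) {
  if (is.character(protocol)) protocol <- load_protocol(protocol)
  if (is.null(groups)) groups <- names(protocol$groups)
  stopifnot(n_replicates >= 1)
  set.seed(master_seed)
  seeds <- sample.int(2147483646L, n_replicates)
  out <- purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
    seed <- seeds[rep_i]
    set.seed(seed)
    net <- build_network(spec, seed)
    net <- calibrate_home(net)
    purrr::map_dfr(groups, function(g) {
      dplyr::bind_cols(
        tibble::tibble(replicate = rep_i, seed = seed),
        run_group(protocol, g, seed = seed, spec = spec, network = net,
                  stress = stress, shock_gain = shock_gain))
    })
  })
  class(out) <- c("fearsim_replicates", class(out))
  attr(out, "protocol") <- protocol$name
  attr(out, "master_seed") <- master_seed
  out
}

#' Tukey boxplot summary
#'
#' Five-number summary with 1.5 IQR whiskers: quartiles by linear
#' interpolation (the common default quantile rule), whiskers at the most
#' extreme observations within `q1 - 1.5 IQR` / `q3 + 1.5 IQR`, values
#' beyond the whisker fences listed as outliers.
#'
#' @param values numeric vector (>= 1 value).
#' @return One-row tibble with `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `n` and an `outliers` list column.
#' @export
#' @examples
#' boxplot_summary(c(1:9, 50))
boxplot_summary <- function(values) {
  if (length(values) == 0) stop("empty input")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  tibble::tibble(
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = min(values[inside]),
    whisker_high = max(values[inside]),
    n = length(values),
    outliers = list(sort(values[!inside])))
}

#' Smallest replicate count with a stable confidence interval
#'
#' Finds the smallest `n` (at least 3) such that for every `m >= n` the
#' t-based confidence-interval half-width of the running mean of the
#' per-replicate means is at most `tolerance` percentage points.
#'
#' @param per_replicate_means per-replicate mean freezing values, in
#'   replicate order.
#' @param ci_level confidence level.
#' @param tolerance maximal CI half-width (percentage points).
#' @return The smallest stable `n`, or `NA` if the criterion is never
#'   reached within the supplied replicates.
#' @export
convergence_analysis <- function(per_replicate_means, ci_level = 0.95,
                                 tolerance = 5) {
  x <- per_replicate_means
  if (length(x) < 3) stop("need at least 3 replicates")
  half <- vapply(seq_along(x), function(m) {
    if (m < 2) return(Inf)
    qt(1 - (1 - ci_level) / 2, m - 1) * sd(x[seq_len(m)]) / sqrt(m)
  }, numeric(1))
  ok <- rev(cumprod(rev(half <= tolerance))) > 0  # TRUE iff all m >= n ok
  n <- which(ok)[1]
  if (is.na(n)) return(NA_integer_)
  max(3L, as.integer(n))
}

#' Export a replicate table and its summaries
#'
#' Writes the episode table as CSV and a JSON manifest (protocol, master
#' seed, group/phase boxplot summaries) for reproducibility.
#'
#' @param table a [run_replicates()] tibble.
#' @param path output directory (created if needed).
#' @param summaries optional precomputed summaries; by default
#'   per-(group, phase) boxplot summaries are computed from `table`.
#' @return Invisibly, the paths written.
#' @export
export_results <- function(table, path, summaries = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(path, "episodes.csv")
  flat <- dplyr::select(as_tibble(table), -dplyr::any_of("spike_totals"))
  write.csv(flat, csv, row.names = FALSE)
  if (is.null(summaries) && nrow(table) > 0) {
    summaries <- table |>
      dplyr::group_by(.data$group, .data$phase) |>
      dplyr::summarise(
        boxplot_summary(.data$freezing_percent), .groups = "drop") |>
      dplyr::mutate(outliers = purrr::map(.data$outliers, identity))
  }
  manifest <- list(
    protocol = attr(table, "protocol"),
    master_seed = attr(table, "master_seed"),
    n_rows = nrow(table),
    summaries = summaries)
  js <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv, js))
}

#' Full replicate battery across several protocols
#'
#' Runs `n_replicates` independent simulations of several protocols with a
#' shared Home-calibrated baseline per replicate: the network is built and
#' calibrated once per replicate and that weight state is the starting
#' point for every group of every protocol, mirroring the baseline
#' procedure of the behavioral design.
#'
#' @param protocols character vector of protocol names (default: all).
#' @param n_replicates replicates per protocol.
#' @param master_seed integer master seed.
#' @param spec network spec.
#' @param stress enable the stress-hormone system.
#' @param shock_gain shock intensity multiplier.
#' @param groups optional named list (protocol -> group ids) restricting
#'   which groups run; protocols absent from the list run all groups.
#' @return A `fearsim_replicates` tibble covering all protocols.
#' @export
run_battery <- function(protocols = list_protocols(), n_replicates = 15L,
                        master_seed = 1L, spec = default_network_spec(),
                        stress = TRUE, shock_gain = 1, groups = NULL) {
  set.seed(master_seed)
  seeds <- sample.int(2147483646L, n_replicates)
  specs <- lapply(protocols, load_protocol)
  out <- purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
    seed <- seeds[rep_i]
    set.seed(seed)
    net <- build_network(spec, seed)
    net <- calibrate_home(net)
    purrr::map_dfr(specs, function(pr) {
      gset <- groups[[pr$name]] %||% names(pr$groups)
      purrr::map_dfr(gset, function(g) {
        dplyr::bind_cols(
          tibble::tibble(replicate = rep_i, seed = seed),
          run_group(pr, g, seed = seed, spec = spec, network = net,
                    stress = stress, shock_gain = shock_gain))
      })
    })
  })
  class(out) <- c("fearsim_replicates", class(out))
  attr(out, "protocol") <- paste(protocols, collapse = "+")
  attr(out, "master_seed") <- master_seed
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a replicate battery
#'
#' One row per (group, phase) with the boxplot summary of the phase's
#' freezing values (all episodes, all replicates).
#'
#' @param x a `fearsim_replicates` tibble.
#' @param ... unused.
#' @return A tibble of per-phase summaries.
#' @exportS3Method generics::tidy
tidy.fearsim_replicates <- function(x, ...) {
  x |>
    dplyr::group_by(.data$group, .data$phase) |>
    dplyr::summarise(boxplot_summary(.data$freezing_percent),
                     .groups = "drop")
}

#' Glance at a replicate battery
#'
#' @param x a `fearsim_replicates` tibble.
#' @param ... unused.
#' @return A one-row tibble: protocol, replicate count, episode count and
#'   overall freezing range.
#' @exportS3Method generics::glance
glance.fearsim_replicates <- function(x, ...) {
  tibble::tibble(
    protocol = attr(x, "protocol") %||% NA_character_,
    n_replicates = length(unique(x$replicate)),
    n_groups = length(unique(x$group)),
    n_episodes = nrow(x),
    median_freezing = median(x$freezing_percent),
    max_freezing = max(x$freezing_percent))
}

#' Phase-wise freezing boxplots
#'
#' @param object a `fearsim_replicates` tibble.
#' @param ... unused.
#' @return A ggplot: freezing distributions per phase, faceted by group.
#' @exportS3Method ggplot2::autoplot
autoplot.fearsim_replicates <- function(object, ...) {
  df <- as_tibble(object)
  df$phase <- factor(df$phase, levels = unique(df$phase))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase,
                                   y = .data$freezing_percent)) +
    ggplot2::geom_boxplot(outlier.shape = 3, outlier.colour = "red") +
    ggplot2::facet_wrap(~group, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "freezing (%)",
                  title = attr(object, "protocol")) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Hormone response curves
#'
#' Plots the tonic norepinephrine and corticosteroid levels over the two
#' hours following a stress onset, and the CA1 sparsity schedule.
#'
#' @param t_max minutes after onset to plot.
#' @return A ggplot.
#' @export
plot_hormone_curves <- function(t_max = 150) {
  t <- seq(0, t_max, by = 0.25)
  df <- tibble::tibble(
    t = rep(t, 3),
    level = c(beta_ne(t), beta_cort(t), ca1_sparsity(t)),
    curve = rep(c("beta_NE", "beta_CORT", "CA1 sparsity"), each = length(t)))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$level,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "minutes since stress onset", y = "level",
                  colour = NULL) +
    ggplot2::theme_bw()
}
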