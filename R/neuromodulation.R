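#' Tonic norepinephrine level after a stress onset
#'
#' Single-transient rectified-sine curve
#' \deqn{\beta_{NE}(t) = 0.3853\,\sin(2\pi t/60) + 0.7706\,|\sin(2\pi t/60)|}
#' evaluated for `t` in minutes within one 60-minute period after the
#' stress onset; zero afterwards (the transient does not repeat). The
#' construction `a sin + 2a|sin|` is non-negative everywhere and peaks at
#' 1.1559 at t = 15 min.
#'
#' @param t_since_onset minutes since the stress onset (>= 0); vectorized.
#' @return Tonic NE level (dimensionless, >= 0).
#' @export
#' @examples
#' beta_ne(15) # 0.3853 + 0.7706
beta_ne <- function(t_since_onset) {
  if (any(t_since_onset < 0, na.rm = TRUE))
    stop("t_since_onset must be >= 0")
  s <- sin(2 * pi * t_since_onset / 60)
  out <- 0.3853 * s + 0.7706 * abs(s)
  out[t_since_onset > 60] <- 0
  out[is.na(t_since_onset)] <- 0
  out
}

#' Tonic corticosteroid level after a stress onset
#'
#' Same rectified-sine shape as [beta_ne()] at double the period
#' (120 minutes), modeling the slower hormonal arm of the stress
#' response; zero outside one period.
#'
#' @inheritParams beta_ne
#' @return Tonic corticosteroid level (dimensionless, >= 0).
#' @export
beta_cort <- function(t_since_onset) {
  if (any(t_since_onset < 0, na.rm = TRUE))
    stop("t_since_onset must be >= 0")
  s <- sin(2 * pi * t_since_onset / 120)
  out <- 0.3853 * s + 0.7706 * abs(s)
  out[t_since_onset > 120] <- 0
  out[is.na(t_since_onset)] <- 0
  out
}

#' CA1 sparsity fraction under corticosteroid influence
#'
#' Fraction of CA1 neurons permitted to stay active: 10% at baseline,
#' rising linearly to the 50% saturation value at 40 minutes after a
#' stress onset, holding until the corticosteroid window closes at
#' 120 minutes, then returning to baseline.
#'
#' @param t_since_onset minutes since the stress onset; `NA`/`NULL` means
#'   no active stress.
#' @return Sparsity fraction in `[0.10, 0.50]`.
#' @export
#' @examples
#' ca1_sparsity(NA)  # 0.10 baseline
#' ca1_sparsity(40)  # 0.50 saturation
ca1_sparsity <- function(t_since_onset) {
  if (is.null(t_since_onset) || length(t_since_onset) == 0) return(0.10)
  t <- t_since_onset
  out <- rep(0.10, length(t))
  ramp <- !is.na(t) & t >= 0 & t < 40
  out[ramp] <- 0.10 + (0.50 - 0.10) * t[ramp] / 40
  hold <- !is.na(t) & t >= 40 & t <= 120
  out[hold] <- 0.50
  out
}

#' Hormone-gated input to a prefrontal population
#'
#' The neuromodulated input: the hormonal-influence term is scaled by
#' `(1 + beta)` and combined with the ordinary signed synaptic sums,
#' \eqn{I = (1+\beta) I_{inf} + I_{exc} - I_{inh}}.
#'
#' @param i_inf hormonal-influence current (the locus-coeruleus drive).
#' @param beta tonic hormone level (>= 0).
#' @param exc_sum,inhib_sum summed excitatory / inhibitory inputs
#'   (both passed as magnitudes; the inhibitory sum is subtracted).
#' @return Modulated input current.
#' @export
#' @examples
#' modulated_input(10e-12, 1, 5e-12, 3e-12) # 22 pA
modulated_input <- function(i_inf, beta, exc_sum = 0, inhib_sum = 0) {
  stopifnot(all(beta >= 0))
  (1 + beta) * i_inf + exc_sum - inhib_sum
}

#' Behavioral clock and stress state
#'
#' Tracks minute-scale behavioral time, stress onsets and the cumulative
#' count of shock-paired episodes. Stress begins (an onset is recorded)
#' when the shock counter reaches `trigger_threshold` (15 shock-paired
#' episodes by default); only the most recent onset drives the hormone
#' curves.
#'
#' @param stress_enabled logical; when `FALSE` hormones stay at baseline.
#' @param trigger_threshold shock-paired episodes needed to trigger stress.
#' @param minutes_per_episode behavioral minutes per simulated episode.
#' @return A `fearsim_hormone_state` list.
#' @export
hormone_state <- function(stress_enabled = TRUE, trigger_threshold = 15L,
                          minutes_per_episode = 1) {
  structure(list(clock = 0, onsets = numeric(0),
                 shock_counter = 0L,
                 stress_enabled = isTRUE(stress_enabled),
                 trigger_threshold = as.integer(trigger_threshold),
                 minutes_per_episode = minutes_per_episode),
            class = "fearsim_hormone_state")
}

#' Minutes since the most recent stress onset
#'
#' @param state a [hormone_state()] or `NULL`.
#' @return Minutes since the last onset, or `NA` when no stress is active.
#' @export
time_since_stress <- function(state) {
  if (is.null(state) || length(state$onsets) == 0) return(NA_real_)
  state$clock - max(state$onsets)
}

#' Advance the behavioral clock
#'
#' @param state a [hormone_state()].
#' @param minutes duration to advance (>= 0).
#' @return The updated state.
#' @export
advance_clock <- function(state, minutes) {
  stopifnot(minutes >= 0)
  state$clock <- state$clock + minutes
  state
}

#' Register a shock-paired episode and trigger stress at the threshold
#'
#' Increments the cumulative shock counter; when it reaches the threshold
#' (exactly; repeated calls past the threshold are idempotent) a stress
#' onset is recorded at the current clock.
#'
#' @param state a [hormone_state()].
#' @return The updated state.
#' @export
stress_trigger <- function(state) {
  state$shock_counter <- state$shock_counter + 1L
  if (state$stress_enabled &&
      state$shock_counter == state$trigger_threshold) {
    state$onsets <- c(state$onsets, state$clock)
  }
  state
}

#' Current hormone levels
#'
#' @param state a [hormone_state()] or `NULL`.
#' @return List with `beta_ne`, `beta_cort`, `ca1_fraction` and
#'   `t_since_onset`.
#' @export
hormone_levels <- function(state) {
  t <- time_since_stress(state)
  if (!is.null(state) && !state$stress_enabled) t <- NA_real_
  list(beta_ne = if (is.na(t)) 0 else beta_ne(t),
       beta_cort = if (is.na(t)) 0 else beta_cort(t),
       ca1_fraction = ca1_sparsity(t),
       t_since_onset = t)
}
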