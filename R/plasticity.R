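#' STDP parameters
#'
#' Pair-based spike-timing-dependent plasticity with soft bounds. With
#' \eqn{\Delta t = t_{pre} - t_{post}} (steps), a pre-before-post pairing
#' (\eqn{\Delta t \le 0}) potentiates and a post-before-pre pairing
#' (\eqn{\Delta t > 0}) depresses:
#' \deqn{\Delta\omega = \begin{cases}
#'   (\omega_{max}-\omega)\,A_+\,e^{\Delta t/\tau_+}/\tau_\omega & \Delta t \le 0\\
#'   (\omega_{min}-\omega)\,|A_-|\,e^{-\Delta t/\tau_-}/\tau_\omega & \Delta t > 0
#' \end{cases}}
#' Both branches decay with the pairing interval and the soft bounds
#' \eqn{[\omega_{min}, \omega_{max}]} make increments vanish at the rails.
#' The default LTP amplitude is three times the LTD amplitude.
#'
#' A zero LTD time constant is degenerate (the depression window would be
#' instantaneous/divergent) and is rejected; the default mirrors the LTP
#' window.
#'
#' @param a_plus LTP amplitude (dimensionless).
#' @param a_minus LTD amplitude; its magnitude sets the depression rate and
#'   the conventional sign is negative.
#' @param tau_w weight-adaptation time constant (steps).
#' @param tau_plus,tau_minus LTP / LTD pairing windows (steps).
#' @param w_min,w_max weight bounds.
#' @return A `fearsim_stdp_params` list.
#' @export
stdp_params <- function(a_plus = 1.2, a_minus = -0.4, tau_w = 10,
                        tau_plus = 10, tau_minus = 10,
                        w_min = 0, w_max = 10) {
  if (tau_minus <= 0)
    stop("tau_minus must be > 0: a zero LTD window is degenerate; ",
         "configure a positive depression time constant")
  stopifnot(tau_w > 0, tau_plus > 0, w_min < w_max)
  structure(list(a_plus = a_plus, a_minus = a_minus, tau_w = tau_w,
                 tau_plus = tau_plus, tau_minus = tau_minus,
                 w_min = w_min, w_max = w_max),
            class = "fearsim_stdp_params")
}

#' One-pairing STDP weight increment
#'
#' Evaluates the soft-bound pair rule for a single pre/post pairing;
#' vectorized over weights and pairing intervals.
#'
#' @param w current weight(s), within `[w_min, w_max]`.
#' @param delta_t pairing interval(s) `t_pre - t_post` in steps; `<= 0`
#'   potentiates, `> 0` depresses.
#' @param params an [stdp_params()].
#' @return Weight increment(s); potentiation is `>= 0`, depression `<= 0`.
#' @export
#' @examples
#' p <- stdp_params()
#' stdp_delta(5, -2, p)  # potentiation
#' stdp_delta(5, 2, p)   # depression
stdp_delta <- function(w, delta_t, params) {
  stopifnot(all(is.finite(delta_t)))
  pot <- (params$w_max - w) * params$a_plus *
    exp(delta_t / params$tau_plus) / params$tau_w
  dep <- (params$w_min - w) * abs(params$a_minus) *
    exp(-delta_t / params$tau_minus) / params$tau_w
  ifelse(delta_t <= 0, pot, dep)
}

#' Nearest-neighbour STDP update of a projection
#'
#' Applies the pair rule with nearest-neighbour pairing for one simulation
#' step: each postsynaptic spike is paired with every presynaptic neuron's
#' most recent spike (potentiation; a same-step presynaptic spike counts
#' with \eqn{\Delta t = 0}), and each presynaptic spike is paired with
#' every postsynaptic neuron's most recent *earlier* spike (depression;
#' same-step postsynaptic spikes are excluded, so coincident pairs only
#' potentiate). Entries without a partner spike are unchanged. Potentiation
#' is applied before depression. Results are clipped to the bounds.
#'
#' @param weights `n_pre x n_post` weight matrix.
#' @param pre_last_spike,post_last_spike most recent spike step per neuron
#'   *before* this step (-1 = never).
#' @param spiked_pre,spiked_post logical spike flags for the current step.
#' @param params an [stdp_params()].
#' @param step current step index.
#' @return The updated weight matrix.
#' @export
update_projection <- function(weights, pre_last_spike, post_last_spike,
                              spiked_pre, spiked_post, params, step) {
  if (nrow(weights) != length(pre_last_spike) ||
      ncol(weights) != length(post_last_spike) ||
      length(spiked_pre) != length(pre_last_spike) ||
      length(spiked_post) != length(post_last_spike))
    stop("dimension mismatch between weights and spike vectors")
  fp <- params$a_plus / params$tau_w
  fm <- abs(params$a_minus) / params$tau_w
  e_pre <- ifelse(spiked_pre, 1,
                  ifelse(pre_last_spike >= 0,
                         exp((pre_last_spike - step) / params$tau_plus), 0))
  for (j in which(spiked_post)) {
    weights[, j] <- weights[, j] + (params$w_max - weights[, j]) * fp * e_pre
  }
  e_post <- ifelse(spiked_post | post_last_spike < 0, 0,
                   exp(-(step - post_last_spike) / params$tau_minus))
  for (i in which(spiked_pre)) {
    weights[i, ] <- weights[i, ] + (params$w_min - weights[i, ]) * fm * e_post
  }
  clip_weights(weights, params)
}

#' Clamp weights to the STDP dynamic range
#'
#' @param weights weight matrix or vector.
#' @param params an [stdp_params()] (only `w_min`, `w_max` are used).
#' @return Elementwise clamp of `weights` to `[w_min, w_max]`.
#' @export
clip_weights <- function(weights, params) {
  pmin(pmax(weights, params$w_min), params$w_max)
}
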