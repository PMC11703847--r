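#' Membrane parameters for one integrate-and-fire population
#'
#' Conductance-based integrate-and-fire constants. The membrane obeys
#' \deqn{\tau dV/dt = (E - V) + \frac{g_E}{g_{leak}}(E_E - V) +
#'       \frac{g_I}{g_{leak}}(E_I - V) + \eta}
#' with \eqn{\eta \sim N(\mu, \sigma)} drawn once per neuron per step, and a
#' threshold/reset rule \eqn{V \to V_{reset}} when \eqn{V > V_{th}}. All
#' values are SI (volts, siemens, farads, seconds); noise is in volts per
#' integration step.
#'
#' The printed capacitance (5.5 pF) and leak conductance (10 nS) give
#' C/g_leak = 0.55 ms, while the model's step arithmetic (8,000 steps over
#' 4,000 ms) requires tau = 0.5 ms. The explicit tau governs integration;
#' `c_m` and `g_leak` are kept as physical metadata (g_leak also normalizes
#' synaptic currents).
#'
#' @param c_m membrane capacitance (F).
#' @param g_leak leak conductance (S).
#' @param e_leak leak (resting) reversal potential (V).
#' @param e_exc,e_inh excitatory / inhibitory synaptic reversal potentials (V).
#' @param v_th firing threshold (V).
#' @param v_reset post-spike reset potential (V).
#' @param v_peak cosmetic spike peak for voltage traces (V).
#' @param tau membrane time constant, also the integration step (s).
#' @param noise_mean,noise_sd membrane noise mean / sd per step (V).
#' @param refractory_steps steps clamped at `v_reset` after a spike.
#' @return A `fearsim_neuron_params` list.
#' @export
#' @examples
#' p <- neuron_params()
#' p$tau
neuron_params <- function(c_m = 5.5e-12, g_leak = 10e-9,
                          e_leak = -70e-3, e_exc = 0, e_inh = -80e-3,
                          v_th = -50e-3, v_reset = -70e-3, v_peak = 0,
                          tau = 0.5e-3, noise_mean = 0, noise_sd = 0.5e-3,
                          refractory_steps = 1L) {
  stopifnot(c_m > 0, g_leak > 0, tau > 0, noise_sd >= 0,
            v_reset <= v_th, e_inh <= e_leak, e_leak <= e_exc,
            refractory_steps >= 0)
  structure(list(c_m = c_m, g_leak = g_leak, e_leak = e_leak,
                 e_exc = e_exc, e_inh = e_inh, v_th = v_th,
                 v_reset = v_reset, v_peak = v_peak, tau = tau,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 refractory_steps = as.integer(refractory_steps)),
            class = "fearsim_neuron_params")
}

#' Initialize the state of one population
#'
#' Neurons start at the resting potential with no spike history.
#'
#' @param n number of neurons.
#' @param params a [neuron_params()] object.
#' @return A `fearsim_layer_state` list with membrane voltages `v`, the
#'   current-step spike flags `spiked`, refractory counters
#'   `refractory_remaining`, last-spike bookkeeping `last_spike`
#'   (-1 = never), and `step_index`.
#' @export
layer_state <- function(n, params = neuron_params()) {
  stopifnot(n >= 1)
  structure(list(v = rep(params$e_leak, n),
                 spiked = rep(FALSE, n),
                 refractory_remaining = rep(0L, n),
                 last_spike = rep(-1L, n),
                 step_index = 0L),
            class = "fearsim_layer_state")
}

#' Synaptic driving-force current
#'
#' Ohmic synaptic current: conductance times driving force,
#' \eqn{I = g_{syn} (E_{syn} - V)}, evaluated elementwise.
#'
#' @param pre_activity summed synaptic conductance per postsynaptic neuron
#'   (S); scalars are recycled.
#' @param v_post postsynaptic membrane potentials (V).
#' @param e_syn synaptic reversal potential (V), typically `e_exc` or `e_inh`.
#' @return Current vector (A); sign follows the driving force.
#' @export
#' @examples
#' synaptic_drive(1e-9, -70e-3, 0) # 70 pA
synaptic_drive <- function(pre_activity, v_post, e_syn) {
  if (!all(is.finite(pre_activity))) stop("non-finite synaptic conductance")
  if (length(pre_activity) > 1 && length(pre_activity) != length(v_post))
    stop("dimension mismatch: pre_activity has length ",
         length(pre_activity), ", v_post has length ", length(v_post))
  pre_activity * (e_syn - v_post)
}

#' One forward-Euler membrane update
#'
#' Advances the membrane equation by one step of length `dt` (default: the
#' membrane time constant, i.e. one model iteration). Neurons in their
#' refractory period are clamped at `v_reset` and their counter
#' decremented; they receive neither input nor noise.
#'
#' @param state a [layer_state()].
#' @param i_exc,i_inh excitatory / inhibitory synaptic currents (A).
#' @param params a [neuron_params()].
#' @param noise optional externally supplied per-neuron noise (V per step);
#'   when `NULL`, drawn from `N(noise_mean, noise_sd)` via the R RNG.
#' @param dt integration step (s); smaller steps give the usual first-order
#'   Euler convergence toward the exact exponential relaxation. Voltages
#'   are floored at the inhibitory reversal potential `e_inh` (conductance
#'   dynamics cannot hyperpolarize below the lowest reversal).
#' @return The updated state.
#' @export
integrate_step <- function(state, i_exc = 0, i_inh = 0,
                           params = neuron_params(), noise = NULL,
                           dt = params$tau) {
  n <- length(state$v)
  i_exc <- rep_len(i_exc, n); i_inh <- rep_len(i_inh, n)
  bad <- which(!is.finite(i_exc) | !is.finite(i_inh) | !is.finite(state$v))
  if (length(bad) > 0)
    stop("non-finite membrane input at neuron index ", bad[1])
  if (is.null(noise)) {
    noise <- if (params$noise_sd == 0 && params$noise_mean == 0) rep(0, n)
             else rnorm(n, params$noise_mean, params$noise_sd)
  }
  frac <- dt / params$tau
  free <- state$refractory_remaining <= 0L
  dv <- frac * ((params$e_leak - state$v) +
                (i_exc + i_inh) / params$g_leak + noise)
  state$v[free] <- pmax(state$v[free] + dv[free], params$e_inh)
  state$v[!free] <- params$v_reset
  state$refractory_remaining[!free] <- state$refractory_remaining[!free] - 1L
  state$step_index <- state$step_index + 1L
  state
}

#' Threshold crossing, spike flagging and reset
#'
#' Neurons above threshold are marked as spiking (their output is the
#' cosmetic peak `v_peak` for traces), reset to `v_reset`, and enter the
#' refractory period. Downstream computation uses the boolean flags only.
#'
#' @param state a [layer_state()] after [integrate_step()].
#' @param params a [neuron_params()].
#' @return The updated state; `state$spiked` holds this step's spikes.
#' @export
apply_spike_reset <- function(state, params = neuron_params()) {
  fired <- state$refractory_remaining <= 0L & state$v > params$v_th
  state$spiked <- fired
  state$v_out <- ifelse(fired, params$v_peak, state$v)
  state$v[fired] <- params$v_reset
  state$refractory_remaining[fired] <- params$refractory_steps
  state$last_spike[fired] <- state$step_index - 1L
  state
}
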