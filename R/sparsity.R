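#' k-winner-take-all parameters
#'
#' Gating of a layer's input drive: the k most excited neurons keep their
#' (gain-scaled) drive while the rest receive a global inhibitory term
#' that makes their net drive non-positive.
#'
#' @param k number of permitted winners.
#' @param w_exc excitatory gain applied to winners.
#' @param w_inib inhibitory gain of the global suppression term.
#' @param e_ref driving-force reference potential (V) for the inhibitory
#'   term.
#' @return A `fearsim_kwta_params` list.
#' @export
kwta_params <- function(k, w_exc = 1, w_inib = 10, e_ref = -70e-3) {
  stopifnot(k >= 1, w_exc >= 0, w_inib >= 0)
  structure(list(k = as.integer(k), w_exc = w_exc, w_inib = w_inib,
                 e_ref = e_ref),
            class = "fearsim_kwta_params")
}

#' Select the k most excited neurons
#'
#' Deterministic under ties: the lower index wins, so top-k sets are
#' nested in k.
#'
#' @param excitation per-neuron excitation score.
#' @param k number of winners, `1 <= k <= length(excitation)`.
#' @return Integer indices of the winners, in ascending index order.
#' @export
#' @examples
#' select_winners(c(0.1, 0.9, 0.3), 1)
select_winners <- function(excitation, k) {
  n <- length(excitation)
  if (k > n) stop("k (", k, ") exceeds layer size (", n, ")")
  if (k < 1) stop("k must be >= 1")
  sort(order(-excitation, seq_len(n))[seq_len(k)])
}

#' Gate a layer's input drive through k-WTA
#'
#' Winners keep their `w_exc`-scaled drive; every non-winner receives the
#' summed global inhibition \eqn{-w_{inib}\sum_{i \in winners}(V_i - E)^+}
#' and is floored at zero net drive, so non-winners never receive positive
#' drive.
#'
#' @param input_current per-neuron input drive (any consistent unit).
#' @param winners indices from [select_winners()] on the same vector.
#' @param params a [kwta_params()].
#' @param v optional membrane potentials (V) used for the inhibitory term;
#'   when absent the winners' positive drives are used instead.
#' @return Gated drive vector of the same length.
#' @export
apply_kwta <- function(input_current, winners, params, v = NULL) {
  out <- input_current
  inhib <- if (!is.null(v)) {
    params$w_inib * sum(pmax(v[winners] - params$e_ref, 0))
  } else {
    params$w_inib * sum(pmax(input_current[winners], 0))
  }
  loser <- setdiff(seq_along(input_current), winners)
  out[winners] <- params$w_exc * input_current[winners]
  out[loser] <- pmin(0, input_current[loser] - inhib)
  out
}

#' Current sparsity level of a region
#'
#' Returns the k-WTA winner count for a region. Hippocampal subfields use
#' configured fractions of the receiving layer (DG 30%, CA3 5%); CA1's
#' fraction is time-varying with stress via [ca1_sparsity()] (10% baseline,
#' 50% at saturation); single-signal output layers (CeM, CeL) use k = 1;
#' regions without a configured rule perform pure synaptic integration
#' (k = 0, no gating).
#'
#' @param network a built [build_network()] object (or a network spec).
#' @param region region name.
#' @param hormone a [hormone_state()] or `NULL` for no stress.
#' @return Integer winner count `k` (0 = no k-WTA for this region).
#' @export
layer_sparsity <- function(network, region, hormone = NULL) {
  spec <- if (inherits(network, "fearsim_network")) network$spec else network
  reg <- spec$regions[[region]]
  if (is.null(reg)) stop("unknown region: ", region)
  if (identical(region, "CA1")) {
    frac <- ca1_sparsity(time_since_stress(hormone))
    return(as.integer(round(frac * reg$n)))
  }
  if (!is.null(reg$k)) return(as.integer(reg$k))
  if (!is.null(reg$sparsity_fraction))
    return(as.integer(round(reg$sparsity_fraction * reg$n)))
  0L
}
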