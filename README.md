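# fearsim

`fearsim` is a spiking-network simulator of the rodent fear and stress
circuit, for computational neuroscientists who want to run the standard
fear-conditioning behavioral designs *in silico*. Twenty populations of
conductance-based integrate-and-fire neurons — entorhinal cortex (II/V),
dentate gyrus, CA3, CA1, prelimbic (PL) and infralimbic (IL) cortex,
nucleus reuniens, and the amygdalar micro-circuit (LA with PV/CCK
interneurons, basal fear/extinction populations BA_F/BA_E, intercalated
clusters ITC_D/ITC_V, and the central nuclei CeL/CeM) — are wired from a
declarative YAML specification of sizes, signed projections and weight
means, and driven by four stimulus channels: a binary context code, a
tone (CS), a footshock (US) and a tonic locus-coeruleus unit.

The core model:

* **Membrane dynamics.** Each neuron follows
  `tau dV/dt = (E - V) + (g_E/g_leak)(E_E - V) + (g_I/g_leak)(E_I - V) + eta`
  with `tau = 0.5 ms` (also the integration step; a 4,000 ms episode is
  8,000 steps), threshold −50 mV, reset −70 mV, and per-step Gaussian
  membrane noise. The episode engine advances each step with the exact
  relaxation of this equation under frozen conductances.
* **Plasticity.** Pair-based nearest-neighbour STDP with soft bounds on
  the sensory and associative afferents:
  `dw = (w_max - w) A+ exp(dt/tau+) / tau_w` for pre-before-post pairs
  (`dt = t_pre - t_post <= 0`), and
  `dw = (w_min - w)|A-| exp(-dt/tau-) / tau_w` for post-before-pre,
  with `A+ = 1.2 = 3|A-|`.
* **Sparse coding.** k-winner-take-all gating in the hippocampus (DG
  30%, CA3 5%, CA1 10%); CA1's fraction rises to 50% under
  corticosteroid influence.
* **Neuromodulation.** After the fifteenth shock-paired episode, tonic
  norepinephrine and corticosteroid transients
  `beta(t) = 0.3853 sin(2 pi t/P) + 0.7706 |sin(2 pi t/P)|`
  (P = 60 / 120 min) gate the locus-coeruleus drive to PL/IL and the
  CA1 sparsity schedule.
* **Behavior.** Freezing is the percentage of 125 ms theta windows with
  at least one CeM spike. Five packaged protocols transcribe the
  standard designs: contextual fear conditioning with renewal (`cfc`),
  shock magnitude (`shock_magnitude`), stress-enhanced fear learning
  (`sefl`), shock-stress ordering (`shock_stress`) and the immediate
  extinction deficit (`ied`).

See `vignettes/fear-circuit-model.Rmd` for the full account of the
model, its assumptions and the numerical choices.

## A worked example

Build the default quarter-scale circuit, calibrate its baseline in the
Home environment, and run group 1 of contextual fear conditioning
(5 AX+ acquisition, 15 BX− extinction, 3 AX− renewal test):

```r
library(fearsim)
library(dplyr)

set.seed(1)
net <- build_network(default_network_spec(), seed = 1)
net <- calibrate_home(net)
length(attr(net, "calibration"))   # 10 episodes, all at 0 % freezing

res <- run_group("cfc", "1", seed = 1, network = net)
res |> group_by(phase) |>
  summarise(boxplot_summary(freezing_percent)) |> select(-outliers)
#> # A tibble: 3 x 7
#>   phase median    q1    q3 whisker_low whisker_high     n
#>   <chr>  <dbl> <dbl> <dbl>       <dbl>        <dbl> <int>
#> 1 CFC1   31.2  31.2  31.2        31.2         31.2      5
#> 2 CFC2    3.12  3.12  3.12        3.12         3.12    15
#> 3 CFC3    3.12  3.12  3.12        3.12         3.12     3
```

For this replicate, calibration ends with a quiet baseline (0 %
freezing in Home), the shock episodes drive freezing to 31 % (the CeM
is active throughout the 2,000-step shock window and its margins), and
tone-alone episodes after extinction stay near the floor. Replicates
differ: the circuit sits close to its excitation/inhibition balance
point, so group-level claims are made on medians across replicates
(`run_replicates()`, `run_battery()`), summarized with `tidy()` /
`glance()` and plotted with `autoplot()`.

A thin command-line front end wraps the same functions:

```sh
exec/fearsim list-protocols
exec/fearsim run --protocol cfc --group 1 --replicates 15 --seed 42 --out results/
exec/fearsim analyze results/ --convergence
```

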