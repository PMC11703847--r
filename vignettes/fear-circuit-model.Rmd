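---
title: "A spiking circuit model of fear conditioning, extinction and stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking circuit model of fear conditioning, extinction and stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fearsim)
```

`fearsim` simulates the rodent fear/stress circuit as twenty interacting
populations of conductance-based integrate-and-fire neurons — entorhinal
cortex (layers II and V), dentate gyrus, CA3, CA1, prelimbic and
infralimbic cortex, nucleus reuniens, and the amygdalar micro-circuit
(LA with PV/CCK interneurons, basal fear and extinction populations,
intercalated clusters, lateral and medial central amygdala). Four
stimulus channels drive it: a binary context code, a tone (CS), a
footshock (US), and a tonic locus-coeruleus unit. Freezing behavior is
read out from medial-central-amygdala (CeM) spiking.

## Membrane model and integration

Each neuron follows the conductance-based integrate-and-fire equation

$$\tau \frac{dV}{dt} = (E - V) + \frac{g_E}{g_{leak}}(E_E - V) +
  \frac{g_I}{g_{leak}}(E_I - V) + \eta,$$

with rest/leak reversal $E=-70$ mV, excitatory and inhibitory reversals
$E_E = 0$ mV and $E_I = -80$ mV, threshold $-50$ mV, reset $-70$ mV, a
one-step refractory period, and per-step Gaussian membrane noise
($\sigma = 0.5$ mV). The stated membrane constant $\tau = 0.5$ ms is
also the integration step, so a 4,000 ms behavioral episode is 8,000
steps; the printed capacitance (5.5 pF) and leak conductance (10 nS)
would give $C/g_{leak} = 0.55$ ms and are kept as metadata only, since
the 8,000-step arithmetic pins $\tau$ at 0.5 ms.

Two numerical choices matter at a step as large as $\tau$:

* **Exact one-step relaxation.** The episode engine advances each
  neuron to
  $V' = V^* + (V - V^*)e^{-a}$, where $a = 1 + g_E/g_{leak} +
  g_I/g_{leak}$ and $V^*$ is the conductance-weighted equilibrium
  $(E + E_E\,g_E/g_{leak} + E_I\,g_I/g_{leak})/a$ — the exact solution
  of the membrane equation over one step with frozen conductances.
  Plain forward Euler at step $\tau$ overshoots: strongly inhibited
  neurons are thrown below $E_I$, where the inhibitory driving force
  changes sign and the neuron oscillates and spikes spuriously, so
  inhibition could never veto amygdala output. The exact update is
  unconditionally stable and keeps voltages between the reversal
  potentials. The standalone `integrate_step()` operation remains the
  textbook forward-Euler form (with a configurable sub-step), which is
  what the leak-relaxation convergence tests exercise.
* **Synaptic traces.** Each spike contributes an exponentially decaying
  conductance trace ($\tau_{syn} = 2$ steps) rather than a single-step
  pulse. With one-step pulses and a one-step refractory period, all
  strongly driven populations phase-lock at half the step rate, and
  inhibition landing on a target's refractory steps is silently
  discarded; the short trace spreads every synapse's conductance across
  the phase so that excitation/inhibition balance is actually felt.

## Synaptic organization and conductance scale

Region sizes, the signed afferent template and the weight means are the
published architecture, transcribed in
`inst/extdata/network_default.yaml`. Signs live in the connection
specification; weights are non-negative magnitudes drawn from
$N(\mu, 0.3)$ (clamped to the dynamic range) and masked by a
connectivity fraction where sub-sampling is specified (layer-V
entorhinal afferents at 50%; context afferents at 50% so that
individual EC-II neurons sample different context units and the layer's
response is context-selective).

The tables give weight means but not the physical synaptic conductance
per weight unit, so the package fixes an operating point, chosen once
from a drive analysis and then frozen:

* Per-projection conductance is normalized by the **source's typical
  active pool** (its k-WTA winner count for sparse layers, its designed
  active-unit count for stimulus channels, its size otherwise). A
  projection's impact is then set by its table weight, not by how many
  neurons happen to implement the source population — and the model is
  invariant to the down-scaling of region sizes used in tests.
* `g_total = 0.2` (in units of $g_{leak}$) sets the absolute scale: a
  saturated afferent population with unit weight contributes roughly
  two-thirds of the distance from rest to threshold.
* Inhibitory synapses carry `inh_gain = 2` times the excitatory
  conductance, compensating the 7-fold weaker inhibitory driving force
  near rest ($E - E_I = 10$ mV versus $E_E - E = 70$ mV).
* Stimulus channels carry `ext_gain = 4` times the internal unit, so
  that the naive tone sits just below the LA threshold while the
  conditioned tone sits above it.
* A handful of projections whose functional strength the tables leave
  open (missing weight means, or relays whose raw mean would let one
  pathway trivially dominate) carry an explicit gain multiplier
  (`gmult`) in the configuration: the reuniens feedback to EC-II is
  attenuated so it modulates rather than overwrites the context code;
  the shock input to infralimbic cortex is amplified so the US
  interrupts extinction processing; the prefrontal and hippocampal
  afferents to the infralimbic gate are scaled so that the gate is
  *learning-limited* (see below). All of these are config-visible
  choices, not hidden constants.

## Plasticity

Designated projections are plastic under pair-based, nearest-neighbour
STDP with soft bounds: a pre-before-post pairing at interval
$\Delta t = t_{pre} - t_{post} \le 0$ potentiates by
$(\omega_{max}-\omega) A_+ e^{\Delta t/\tau_+}/\tau_\omega$, a
post-before-pre pairing depresses by
$(\omega_{min}-\omega)|A_-| e^{-\Delta t/\tau_-}/\tau_\omega$, with
$A_+ = 1.2 = 3|A_-|$, $\tau_\omega = \tau_+ = \tau_- = 10$ steps and a
per-projection dynamic range $[0, 5\mu]$. Both branches decay with the
pairing interval and vanish at the rails. A zero LTD window is rejected
at validation as degenerate.

The default plastic set comprises the sensory and associative
afferents: context → EC-II, the trisynaptic chain (EC-II → DG → CA3 →
CA1), tone and shock onto LA, and the CA1 projections to infralimbic,
prelimbic and basal-fear populations. Pathway *amplifiers* (LA → BA_F,
BA_F → PL, the IL ↔ BA_E loop) are static: with tonic stimulus
channels, pair-based STDP drives any co-active plastic projection to
the same activity-independent equilibrium, so leaving amplifier
projections plastic inflates every active pathway by the same factor
and erases the circuit's designed excitation/inhibition ratios —
reciprocal plastic loops even self-ignite from noise coincidences.
Restricting plasticity to the afferent association sites keeps learning
where the behavioral contingencies live.

The extinction gate is deliberately learning-limited: the infralimbic
population's naive drive (prelimbic + naive CA1 + locus coeruleus) sits
just below threshold, so IL fires only on noise excursions; each such
spike potentiates the context-specific CA1 → IL projection, gradually
lifting the *trained context's* IL drive above threshold. Once IL is
active it recruits BA_E and the ventral intercalated cluster, which
vetoes BA_F and silences CeM. Because the gate is context-specific,
extinction in context B need not transfer to context A (renewal), and
because the shock channel inhibits IL during the US window, acquisition
episodes train the gate less than extinction episodes do.

## Sparse coding and neuromodulation

Hippocampal layers are gated by k-winner-take-all on the
driving-force-weighted input: DG keeps 30% of its neurons, CA3 5%, CA1
10% at baseline; winners' excitatory conductance is amplified
(`w_exc = 3`) and non-winners lose their excitatory drive, so their net
input is non-positive. Output-selection layers (CeM, CeL) use $k = 1$
without amplification. CA1's fraction is stress-dependent: after a
stress onset it ramps linearly from 10% to the 50% saturation value at
40 minutes, holds until the corticosteroid window closes at 120
minutes, and returns to baseline.

Stress is triggered by the fifteenth cumulative shock-paired episode.
The tonic hormone levels follow single-transient rectified sine curves,
$\beta(t) = 0.3853\sin(2\pi t/P) + 0.7706\,|\sin(2\pi t/P)|$ with a
60-minute period for norepinephrine and 120 minutes for
corticosteroids; both are non-negative and evaluated only within one
period of the most recent onset. Norepinephrine scales the
locus-coeruleus drive to the prefrontal populations by $(1+\beta_{NE})$;
corticosteroids act through the CA1 sparsity schedule. The behavioral
clock advances one minute per episode and by the stated gaps between
phases (15 minutes or 24 hours in the immediate-extinction design, one
day between phases elsewhere).

## Stimulus encoding

The circuit description leaves the context representation open, so the
package ships a synthetic code: 28 binary context units, with contexts A, B, C
each activating 35% of them at a pairwise Jaccard overlap of 0.2, and a
distinct low-activity (20%) Home pattern disjoint from the three
conditioning contexts. The tone activates all ten CS units; the shock
activates the ten US units during a contiguous 2,000-step window in the
second quarter of the episode, at 1.00 nA on the sensory layer with a
0.01 nA decay per synaptic layer of depth; the locus coeruleus is a
single tonic unit. Patterns are deterministic given the network seed.

## Freezing readout and statistics

Freezing is the percentage of non-overlapping 125 ms theta windows (250
steps at the 8 Hz network rhythm) containing at least one CeM spike.
The readout is deliberately coarse — 32 windows per episode — and is
all-or-nothing within a window, so single-episode freezing is quantized
and distribution-level comparisons are made on medians across
replicates. Replicate batteries derive per-replicate seeds from a
master seed, build and Home-calibrate a fresh network per replicate,
and share that calibrated baseline across every group of every
experiment, as the behavioral design prescribes. Boxplot summaries use
linear-interpolation quartiles with 1.5 IQR whiskers; the convergence
analysis reports the smallest replicate count from which the t-based
95% confidence half-width of the running mean stays within five
percentage points.

## What the tests do and do not show

The test battery runs the five experimental designs at quarter scale
(region sizes divided by four, minimum two neurons, conductances
fan-in-compensated) with fifteen replicates, and a five-replicate
no-shock null battery; unit and oracle tests use a sixteenth-scale
circuit. These sizes are the package's desk-scale study conditions;
`default_network_spec("full")` builds the full architecture.

The synthetic stimuli emulate the structure of the behavioral designs —
context identity and overlap, tone/shock contingency, session timing —
not the sensory statistics of real environments. Passing behavioral
tests therefore show that the implemented circuit mechanisms (shock-
driven amygdala activation, tone association, context-gated extinction,
hormone scheduling) produce the expected direction of effects under the
model's own assumptions; they are not evidence about real rodents.

Known limitations, documented deliberately:

* With tonic stimulus channels, the pair-based STDP equilibrium is
  largely independent of postsynaptic rate, so graded contingency
  effects (for example, freezing that scales smoothly with shock
  count) are weak; contingency is mostly encoded as co-active versus
  never-co-active.
* Several population-level balances sit near threshold by construction,
  so individual replicates can fall into qualitatively different
  regimes; distribution-level orderings at fifteen replicates inherit
  that variability, and some of the distribution-level contrasts of
  the original designs do not emerge robustly at desk scale.
* The weight means define the architecture up to the operating-point
  constants described above; those constants were chosen once from the
  drive analysis and are not fitted to behavioral outcomes.
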