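# Default fear/stress circuit: region sizes, signed connections and weight
# means of the published architecture. Sizes are full-scale reference
# counts; build_network() can scale them down with fan-in compensation.
#
# Units: weight means/sds are dimensionless weight units; one weight unit
# corresponds to g_unit_ns nanosiemens of synaptic conductance. Inhibitory
# synapses carry inh_gain times that conductance (GABAergic conductances
# are large relative to their driving force near rest).
name: fear-stress-circuit
# Operating point (see the methods vignette). Per-projection conductance
# is normalized by the source population's typical active pool (its
# k-WTA winner count for sparse layers, its size otherwise), so that a
# projection's impact is set by its table weight rather than by the
# source's size: gscale = g_total * gains / n_eff(source).  External
# stimulus channels carry ext_gain times the internal unit; inhibitory
# synapses carry inh_gain times their excitatory equivalent, compensating
# the ~7x weaker inhibitory driving force near rest (E - E_I = 10 mV vs
# E_E - E = 70 mV) so intercalated inhibition can veto amygdala output.
g_total: 0.2
ext_gain: 4.0
inh_gain: 2.0

neuron_defaults:
  c_m_pf: 5.5
  g_leak_ns: 10.0
  e_leak_mv: -70.0
  e_exc_mv: 0.0
  e_inh_mv: -80.0
  v_th_mv: -50.0
  v_reset_mv: -70.0
  v_peak_mv: 0.0
  tau_ms: 0.5
  noise_mean_mv: 0.0
  noise_sd_mv: 0.5
  refractory_steps: 1
  tau_syn_steps: 2.0   # synaptic conductance trace time constant (steps)

stdp:
  a_plus: 1.2
  a_minus: -0.4
  tau_w: 10
  tau_plus: 10
  tau_minus: 10
  w_min: 0.0
  w_max_scale: 5.0   # per-projection upper bound = w_max_scale * mu

kwta:
  w_exc: 3.0    # winner amplification of sparse-layer drive
  w_inib: 10.0

# External input populations (stimulus channels; sizes fixed across scales)
externals:
  Context: {size: 28, active: 10}
  CS:      {size: 10, active: 10}
  US:      {size: 10, active: 10}
  LC:      {size: 1,  active: 1}

regions:
  EC_II:   {size: 50}
  DG:      {size: 500, sparsity_fraction: 0.30}
  CA3:     {size: 160, sparsity_fraction: 0.05}
  CA1:     {size: 40,  sparsity_fraction: 0.10}  # time-varying with stress
  EC_V:    {size: 20}
  IL:      {size: 20}
  PL:      {size: 20}
  RE:      {size: 20}
  LA:      {size: 50}
  LA_PV:   {size: 10}
  LA_CCK:  {size: 10}
  BA_CCK:  {size: 10}
  BA_E:    {size: 50}
  BA_F:    {size: 80}
  BA_PV:   {size: 10}
  ITC_D:   {size: 20}
  ITC_V:   {size: 20}   # size mirrors ITC_D (not listed separately)
  CeL_ON:  {size: 10, k: 1, w_exc: 1.0}
  CeL_OFF: {size: 10, k: 1, w_exc: 1.0}
  CeM:     {size: 2,  k: 1, w_exc: 1.0}

# sign: +1 excitatory, -1 inhibitory. mu/sd: weight-init normal parameters.
# default_mu: the published tables list the term without a weight mean;
# mu = 1.0 is the declared default and is flagged at load.
# connectivity < 1: random afferent subsampling (pattern-selective input).
connections:
  - {from: Context, to: EC_II, sign: 1,  mu: 1.2, plastic: true, connectivity: 0.5}
  - {from: RE,      to: EC_II, sign: 1,  mu: 3.0, gmult: 0.2}
  - {from: EC_II,   to: EC_II, sign: -1, mu: 0.3, default_mu: true}
  - {from: EC_II,   to: DG,    sign: 1,  mu: 1.2, plastic: true}
  - {from: DG,      to: DG,    sign: -1, mu: 0.3, default_mu: true}
  - {from: EC_II,   to: CA3,   sign: 1,  mu: 1.2, plastic: true}
  - {from: DG,      to: CA3,   sign: 1,  mu: 1.2, plastic: true}
  - {from: CA3,     to: CA3,   sign: 1,  mu: 1.2}
  - {from: CA3,     to: CA1,   sign: 1,  mu: 1.2, plastic: true}
  - {from: RE,      to: CA1,   sign: 1,  mu: 3.0}
  - {from: BA_F,    to: CA1,   sign: 1,  mu: 1.0}
  - {from: CA1,     to: CA1,   sign: -1, mu: 0.3, default_mu: true}
  - {from: CA1,     to: EC_V,  sign: 1,  mu: 1.2, connectivity: 0.5}
  - {from: EC_II,   to: EC_V,  sign: 1,  mu: 1.2, connectivity: 0.5}
  - {from: EC_V,    to: EC_V,  sign: -1, mu: 0.3, default_mu: true}
  - {from: PL,      to: IL,    sign: 1,  mu: 1.2, gmult: 0.3}
  - {from: BA_E,    to: IL,    sign: 1,  mu: 3.3, gmult: 0.1}
  - {from: US,      to: IL,    sign: -1, mu: 1.2, gmult: 4.0}
  - {from: CA1,     to: IL,    sign: 1,  mu: 1.2, plastic: true, gmult: 0.6, w_max_scale: 2.0}
  - {from: LC,      to: IL,    sign: 1,  mu: 0.1, default_mu: true, modulated: true}
  - {from: RE,      to: PL,    sign: 1,  mu: 2.0}
  - {from: CA1,     to: PL,    sign: 1,  mu: 0.6, plastic: true}
  - {from: BA_F,    to: PL,    sign: 1,  mu: 2.2}
  - {from: LC,      to: PL,    sign: 1,  mu: 0.1, default_mu: true, modulated: true}
  - {from: PL,      to: RE,    sign: 1,  mu: 3.0}
  - {from: IL,      to: RE,    sign: 1,  mu: 3.0}
  - {from: CA1,     to: RE,    sign: 1,  mu: 3.0}
  - {from: CS,      to: LA,    sign: 1,  mu: 0.35, plastic: true, gmult: 1.25}
  - {from: US,      to: LA,    sign: 1,  mu: 1.52, plastic: true}
  - {from: LA_PV,   to: LA,    sign: -1, mu: 0.35}
  - {from: CS,      to: LA_PV, sign: 1,  mu: 0.5}
  - {from: LA_CCK,  to: LA_PV, sign: -1, mu: 1.8}
  - {from: US,      to: LA_CCK, sign: 1, mu: 1.8}
  - {from: IL,      to: BA_E,  sign: 1,  mu: 3.3}
  - {from: BA_CCK,  to: BA_E,  sign: -1, mu: 0.7}
  - {from: LA,      to: BA_CCK, sign: 1, mu: 1.9}
  - {from: BA_F,    to: BA_CCK, sign: 1, mu: 1.9}
  - {from: LA,      to: BA_F,  sign: 1,  mu: 5.0}
  - {from: PL,      to: BA_F,  sign: 1,  mu: 3.6, gmult: 0.05}
  - {from: CA1,     to: BA_F,  sign: 1,  mu: 1.0, default_mu: true, plastic: true, gmult: 0.8}
  - {from: BA_PV,   to: BA_F,  sign: -1, mu: 2.0}
  - {from: ITC_V,   to: BA_F,  sign: -1, mu: 8.0}
  - {from: BA_E,    to: BA_PV, sign: 1,  mu: 2.0}
  - {from: IL,      to: BA_PV, sign: 1,  mu: 1.0, default_mu: true}
  - {from: LA,      to: ITC_D, sign: 1,  mu: 1.0}
  - {from: PL,      to: ITC_D, sign: 1,  mu: 1.0, default_mu: true}
  - {from: BA_E,    to: ITC_V, sign: 1,  mu: 1.0}
  - {from: IL,      to: ITC_V, sign: 1,  mu: 4.0, default_mu: true}
  - {from: ITC_D,   to: ITC_V, sign: -1, mu: 1.0, gmult: 0.6}
  - {from: LA,      to: CeL_ON, sign: 1, mu: 0.8}
  - {from: CeL_ON,  to: CeL_OFF, sign: -1, mu: 0.2}
  - {from: ITC_D,   to: CeL_OFF, sign: -1, mu: 1.0}
  - {from: BA_F,    to: CeM,   sign: 1,  mu: 1.9}
  - {from: ITC_V,   to: CeM,   sign: -1, mu: 1.0}
  - {from: CeL_OFF, to: CeM,   sign: -1, mu: 2.3}
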