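// Episode-level simulation core.
//
// One call advances a built network through n_iter steps with
// conductance-based integrate-and-fire dynamics (exact one-step
// relaxation of the membrane equation under frozen conductances),
// optional k-winner-take-all gating per region, and nearest-neighbour
// pair-based STDP with soft bounds on the projections flagged plastic.
// The R layer owns all configuration, stimulus encoding and readout;
// this file only runs the inner loop.
//
// Conventions shared with the R reference implementation
// (run_episode_r): internal populations propagate an exponentially
// decaying synaptic trace of past spikes with a one-step delay; external
// populations (context, tone, shock, locus coeruleus) act within the
// current step; potentiation is applied before depression within a
// step; a neuron spiking now is excluded from the depression branch
// (delta_t = 0 pairs potentiate only). Arithmetic evaluation order is
// kept identical to the R reference so both loops agree to rounding.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Fast deterministic Gaussian stream (splitmix64 + Box-Muller). The
// membrane noise consumes one draw per neuron per step, which dominates
// the episode cost with library distributions; this generator is
// reproducible for a given seed across runs on the same platform.
struct GaussRng {
  uint64_t state;
  double spare;
  bool has_spare;
  explicit GaussRng(uint64_t seed) : state(seed), spare(0), has_spare(false) {}
  uint64_t next_u64() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double next_unit() {  // uniform in (0, 1]
    return ((next_u64() >> 11) + 1) * (1.0 / 9007199254740992.0);
  }
  double normal() {
    if (has_spare) { has_spare = false; return spare; }
    const double u1 = next_unit(), u2 = next_unit();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double th = 6.283185307179586 * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

struct Region {
  int n;
  double E, EE, EI, Vth, Vreset, nmean, nsd;
  int k;                 // 0 = no k-WTA
  double wexc;
  int refr_steps;
  std::vector<double> v;
  std::vector<int> refr;
  std::vector<int> last;        // last spike step, -1 = never
  std::vector<char> spiked;     // this step
  std::vector<double> trace;    // synaptic conductance trace of past spikes
};

struct Ext {
  int n;
  std::vector<double> act;
  std::vector<int> on;          // indices with positive activity
  bool windowed;
};

struct Conn {
  bool pre_ext;
  int pre, post;
  int sign;
  double gscale;
  double gain;
  bool plastic;
  double wmin, wmax;
  int n_pre, n_post;
  bool inc;                     // static internal: incremental conductance
  std::vector<double> w;        // row-major by presynaptic index:
                                // w[i*n_post + j]
  std::vector<double> gacc;     // accumulated presynaptic trace * weights
};

// [[Rcpp::export]]
List run_episode_core(List regions_in, List conns_in, List ext_in,
                      int n_iter, int us_start, int us_end,
                      List stdp, int readout_region, int seed,
                      double syn_decay) {
  const int n_reg = regions_in.size();
  std::vector<Region> reg(n_reg);
  int max_n = 1;
  for (int r = 0; r < n_reg; ++r) {
    List L = regions_in[r];
    Region &R = reg[r];
    R.n = as<int>(L["n"]);
    R.E = as<double>(L["e_leak"]);  R.EE = as<double>(L["e_exc"]);
    R.EI = as<double>(L["e_inh"]);  R.Vth = as<double>(L["v_th"]);
    R.Vreset = as<double>(L["v_reset"]);
    R.nmean = as<double>(L["noise_mean"]); R.nsd = as<double>(L["noise_sd"]);
    R.k = as<int>(L["k"]); R.wexc = as<double>(L["w_exc"]);
    R.refr_steps = as<int>(L["refractory_steps"]);
    NumericVector v0 = L["v"]; IntegerVector rf0 = L["refr"];
    R.v.assign(v0.begin(), v0.end());
    R.refr.assign(rf0.begin(), rf0.end());
    R.last.assign(R.n, -1);
    R.spiked.assign(R.n, 0);
    R.trace.assign(R.n, 0.0);
    if (R.n > max_n) max_n = R.n;
  }

  const int n_ext = ext_in.size();
  std::vector<Ext> ext(n_ext);
  for (int e = 0; e < n_ext; ++e) {
    List L = ext_in[e];
    NumericVector a = L["activity"];
    ext[e].n = a.size();
    ext[e].act.assign(a.begin(), a.end());
    for (int i = 0; i < ext[e].n; ++i)
      if (ext[e].act[i] > 0) ext[e].on.push_back(i);
    ext[e].windowed = as<bool>(L["windowed"]);
  }

  const int n_conn = conns_in.size();
  std::vector<Conn> con(n_conn);
  std::vector<std::vector<int>> incoming(n_reg);
  for (int c = 0; c < n_conn; ++c) {
    List L = conns_in[c];
    Conn &C = con[c];
    C.pre_ext = as<bool>(L["pre_ext"]);
    C.pre = as<int>(L["pre"]);
    C.post = as<int>(L["post"]);
    C.sign = as<int>(L["sign"]);
    C.gscale = as<double>(L["gscale"]);
    C.gain = as<double>(L["gain"]);
    C.plastic = as<bool>(L["plastic"]);
    C.wmin = as<double>(L["w_min"]);
    C.wmax = as<double>(L["w_max"]);
    NumericMatrix W = L["W"];
    C.n_pre = W.nrow(); C.n_post = W.ncol();
    C.w.resize((size_t)C.n_pre * C.n_post);
    for (int i = 0; i < C.n_pre; ++i)
      for (int j = 0; j < C.n_post; ++j)
        C.w[(size_t)i * C.n_post + j] = W(i, j);
    C.inc = !C.pre_ext && !C.plastic;
    if (C.inc) C.gacc.assign(C.n_post, 0.0);
    incoming[C.post].push_back(c);
  }

  const double a_plus = as<double>(stdp["a_plus"]);
  const double a_minus_abs = std::fabs(as<double>(stdp["a_minus"]));
  const double tau_w = as<double>(stdp["tau_w"]);
  const double tau_p = as<double>(stdp["tau_plus"]);
  const double tau_m = as<double>(stdp["tau_minus"]);
  const double fp = a_plus / tau_w, fm = a_minus_abs / tau_w;
  // pairs older than this contribute < exp(-9) ~ 1e-4 and are skipped
  const int cut_p = (int)std::ceil(9.0 * tau_p);
  const int cut_m = (int)std::ceil(9.0 * tau_m);

  GaussRng gauss((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);

  IntegerVector readout_counts(n_iter);
  IntegerVector spike_totals(n_reg);

  std::vector<double> drive(max_n), gexc(max_n), ginh(max_n);
  std::vector<int> idx(max_n);
  std::vector<char> is_win(max_n);

  for (int t = 0; t < n_iter; ++t) {
    const bool in_window = (t >= us_start && t < us_end);

    for (int r = 0; r < n_reg; ++r) {
      Region &R = reg[r];
      std::fill(gexc.begin(), gexc.begin() + R.n, 0.0);
      std::fill(ginh.begin(), ginh.begin() + R.n, 0.0);

      for (int ci : incoming[r]) {
        const Conn &C = con[ci];
        double *acc = (C.sign > 0) ? gexc.data() : ginh.data();
        if (C.pre_ext) {
          const Ext &X = ext[C.pre];
          if (X.windowed && !in_window) continue;
          for (int i : X.on) {
            const double ag = X.act[i] * C.gscale * C.gain;
            const double *wrow = &C.w[(size_t)i * C.n_post];
            for (int j = 0; j < R.n; ++j) acc[j] += ag * wrow[j];
          }
        } else if (C.inc) {
          // static internal projection: the summed presynaptic-trace *
          // weight products are maintained incrementally (same linear
          // recursion as the per-neuron traces)
          const double g1 = C.gscale * C.gain;
          for (int j = 0; j < R.n; ++j) acc[j] += g1 * C.gacc[j];
        } else {
          const Region &P = reg[C.pre];
          for (int i = 0; i < P.n; ++i) {
            if (P.trace[i] <= 1e-4) continue;
            const double ag = P.trace[i] * C.gscale * C.gain;
            const double *wrow = &C.w[(size_t)i * C.n_post];
            for (int j = 0; j < R.n; ++j) acc[j] += ag * wrow[j];
          }
        }
      }

      // k-WTA: winner selection on the driving-force weighted input;
      // winners keep gain-scaled excitation, non-winners lose theirs
      // (global suppression: their net input is non-positive). With no
      // excitatory drive anywhere the gating is a no-op and is skipped.
      bool any_exc = false;
      for (int j = 0; j < R.n; ++j) if (gexc[j] != 0.0) { any_exc = true; break; }
      if (R.k > 0 && R.k < R.n && any_exc) {
        for (int j = 0; j < R.n; ++j)
          drive[j] = gexc[j] * (R.EE - R.v[j]) + ginh[j] * (R.EI - R.v[j]);
        for (int j = 0; j < R.n; ++j) idx[j] = j;
        std::sort(idx.begin(), idx.begin() + R.n, [&](int a, int b) {
          if (drive[a] != drive[b]) return drive[a] > drive[b];
          return a < b;
        });
        std::fill(is_win.begin(), is_win.begin() + R.n, 0);
        for (int w = 0; w < R.k; ++w) is_win[idx[w]] = 1;
        for (int j = 0; j < R.n; ++j) {
          if (is_win[j]) gexc[j] *= R.wexc;
          else gexc[j] = 0.0;
        }
      }

      // membrane update: exact relaxation of the conductance equation
      // over one step; refractory neurons stay clamped at V_reset.
      // Input-free neurons decay toward rest (cached exp(-1)) and skip
      // the noise draw: at rest they sit tens of noise SDs below
      // threshold, so the draw cannot affect the dynamics.
      static const double e_leak_decay = std::exp(-1.0);
      for (int j = 0; j < R.n; ++j) {
        if (R.refr[j] > 0) {
          R.v[j] = R.Vreset;
          R.refr[j] -= 1;
        } else if (gexc[j] == 0.0 && ginh[j] == 0.0) {
          R.v[j] = R.E + (R.v[j] - R.E) * e_leak_decay + R.nmean;
        } else {
          const double eta = R.nmean + R.nsd * gauss.normal();
          const double a = 1.0 + gexc[j] + ginh[j];
          const double vstar = (R.E + gexc[j] * R.EE + ginh[j] * R.EI) / a;
          R.v[j] = vstar + (R.v[j] - vstar) * std::exp(-a) + eta;
        }
      }

      // threshold, spike, reset
      for (int j = 0; j < R.n; ++j) {
        if (R.refr[j] == 0 && R.v[j] > R.Vth) {
          R.spiked[j] = 1;
          R.v[j] = R.Vreset;
          R.refr[j] = R.refr_steps;
          spike_totals[r] += 1;
        } else R.spiked[j] = 0;
      }
    }

    if (readout_region >= 0) {
      const Region &R = reg[readout_region];
      int cnt = 0;
      for (int j = 0; j < R.n; ++j) cnt += R.spiked[j];
      readout_counts[t] = cnt;
    }

    // STDP on plastic projections (potentiation first, then depression)
    for (int c = 0; c < n_conn; ++c) {
      Conn &C = con[c];
      if (!C.plastic) continue;
      Region &Q = reg[C.post];

      if (C.pre_ext) {
        const Ext &X = ext[C.pre];
        const bool act_now = !(X.windowed && !in_window);
        if (!act_now) continue;
        // potentiation: each post spike against active external units
        for (int j = 0; j < Q.n; ++j) {
          if (!Q.spiked[j]) continue;
          for (int i : X.on) {
            double &w = C.w[(size_t)i * C.n_post + j];
            w += (C.wmax - w) * fp;
          }
        }
        // depression: each active external unit against post last spikes
        for (int j = 0; j < Q.n; ++j) {
          if (Q.spiked[j] || Q.last[j] < 0) continue;
          const int dt = t - Q.last[j];
          if (dt > cut_m) continue;
          const double ex = std::exp(-(double)dt / tau_m);
          for (int i : X.on) {
            double &w = C.w[(size_t)i * C.n_post + j];
            w += (C.wmin - w) * fm * ex;
          }
        }
      } else {
        Region &P = reg[C.pre];
        for (int j = 0; j < Q.n; ++j) {
          if (!Q.spiked[j]) continue;
          for (int i = 0; i < P.n; ++i) {
            double ex;
            if (P.spiked[i]) ex = 1.0;
            else if (P.last[i] >= 0) {
              const int dt = t - P.last[i];
              if (dt > cut_p) continue;
              ex = std::exp(-(double)dt / tau_p);
            } else continue;
            double &w = C.w[(size_t)i * C.n_post + j];
            w += (C.wmax - w) * fp * ex;
          }
        }
        for (int i = 0; i < P.n; ++i) {
          if (!P.spiked[i]) continue;
          double *wrow = &C.w[(size_t)i * C.n_post];
          for (int j = 0; j < Q.n; ++j) {
            if (Q.spiked[j] || Q.last[j] < 0) continue;
            const int dt = t - Q.last[j];
            if (dt > cut_m) continue;
            const double ex = std::exp(-(double)dt / tau_m);
            wrow[j] += (C.wmin - wrow[j]) * fm * ex;
          }
        }
      }
    }

    // commit spikes, decay the synaptic traces and the incremental
    // conductance accumulators
    for (int r = 0; r < n_reg; ++r) {
      Region &R = reg[r];
      for (int j = 0; j < R.n; ++j) {
        if (R.spiked[j]) R.last[j] = t;
        R.trace[j] = R.trace[j] * syn_decay + (R.spiked[j] ? 1.0 : 0.0);
      }
    }
    for (int c = 0; c < n_conn; ++c) {
      Conn &C = con[c];
      if (!C.inc) continue;
      const Region &P = reg[C.pre];
      for (int j = 0; j < C.n_post; ++j) C.gacc[j] *= syn_decay;
      for (int i = 0; i < P.n; ++i) {
        if (!P.spiked[i]) continue;
        const double *wrow = &C.w[(size_t)i * C.n_post];
        for (int j = 0; j < C.n_post; ++j) C.gacc[j] += wrow[j];
      }
    }
  }

  List w_out(n_conn);
  for (int c = 0; c < n_conn; ++c) {
    if (con[c].plastic) {
      Conn &C = con[c];
      NumericMatrix W(C.n_pre, C.n_post);
      for (int i = 0; i < C.n_pre; ++i)
        for (int j = 0; j < C.n_post; ++j) {
          const double w = C.w[(size_t)i * C.n_post + j];
          W(i, j) = std::min(C.wmax, std::max(C.wmin, w));
        }
      w_out[c] = W;
    } else w_out[c] = R_NilValue;
  }
  List v_out(n_reg), refr_out(n_reg);
  for (int r = 0; r < n_reg; ++r) {
    v_out[r] = NumericVector(reg[r].v.begin(), reg[r].v.end());
    refr_out[r] = IntegerVector(reg[r].refr.begin(), reg[r].refr.end());
  }
  return List::create(
    _["weights"] = w_out,
    _["v"] = v_out,
    _["refr"] = refr_out,
    _["readout_counts"] = readout_counts,
    _["spike_totals"] = spike_totals);
}
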