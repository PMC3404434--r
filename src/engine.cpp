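// Fused Forward-Euler engine for the two-layer conductance-based LIF network.
//
// Exploits full connectivity with uniform per-projection parameters:
//  - every non-plastic projection (E->I, I->E, I->I within a layer) delivers
//    the same summed conductance to each of its targets, so a single scalar
//    trace per projection carries the exact per-neuron conductance sum;
//  - the plastic feed-forward projection keeps one summed conductance per
//    postsynaptic neuron, incremented by lambda * Dg[j,i] at each delayed
//    presynaptic spike. Increments use Dg at spike time and decay with the
//    shared tau_EE, which reproduces the naive per-synapse Euler update
//    exactly (delays are uniform within the projection).
// Equivalence with the naive per-synapse formulation is asserted in the test
// suite on a small network.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct PopParams {
  double v0, theta, vH, tauM, g0, sigma;
  int nRef; // refractory steps
};

struct Pop {
  std::vector<double> V;
  std::vector<int> refr;
  PopParams par;
  void init(int n, const PopParams& p) {
    par = p;
    V.assign(n, p.v0);
    refr.assign(n, 0);
  }
  void reset() {
    std::fill(V.begin(), V.end(), par.v0);
    std::fill(refr.begin(), refr.end(), 0);
  }
  int size() const { return (int)V.size(); }
};

struct Recorder {
  std::vector<double> t;
  std::vector<int> layer, pop, neuron, event;
  void add(double tm, int lay, int pp, int nrn, int ev) {
    t.push_back(tm);
    layer.push_back(lay);
    pop.push_back(pp);
    neuron.push_back(nrn + 1); // 1-based for R
    event.push_back(ev);
  }
};

PopParams popFromList(const List& l, double dt) {
  PopParams p;
  p.v0 = as<double>(l["v0_mV"]);
  p.theta = as<double>(l["theta_mV"]);
  p.vH = as<double>(l["vH_mV"]);
  p.tauM = as<double>(l["tau_m_ms"]);
  p.g0 = as<double>(l["g0_nS"]);
  p.sigma = as<double>(l["sigma_mV"]);
  p.nRef = (int)std::ceil(as<double>(l["tau_R_ms"]) / dt - 1e-9);
  return p;
}

} // namespace

// [[Rcpp::export]]
List engine_run(List net, NumericMatrix W_in, List schedule,
                bool learning_on, bool noise, bool noise_inh,
                bool record_input, bool record_output, bool record_inh) {
  const int nE = as<int>(net["n_exc"]);
  const int nI = as<int>(net["n_inh"]);
  const double dt = as<double>(net["dt_ms"]);
  const double vhatE = as<double>(net["vhatE_mV"]);
  const double vhatI = as<double>(net["vhatI_mV"]);

  if (W_in.nrow() != nE || W_in.ncol() != nE)
    stop("plastic weight matrix must be n_exc x n_exc (pre x post)");
  NumericMatrix W = clone(W_in); // W(j, i): presynaptic j, postsynaptic i

  PopParams excP = popFromList(net["exc"], dt);
  PopParams inhP = popFromList(net["inh"], dt);

  // conductance decay factors (Euler) and per-spike increments
  const double kEE = 1.0 - dt / as<double>(net["tau_EE_ms"]);
  const double kIE = 1.0 - dt / as<double>(net["tau_IE_ms"]);
  const double kEI = 1.0 - dt / as<double>(net["tau_EI_ms"]);
  const double kII = 1.0 - dt / as<double>(net["tau_II_ms"]);
  const double incEI = as<double>(net["g_EI_nS"]);
  const double incIE = as<double>(net["g_IE_nS"]);
  const double incII = as<double>(net["g_II_nS"]);
  const double lamEE = as<double>(net["lambda_EE_nS"]);

  // per-projection conduction delays in steps (>= 1: one-step pipeline)
  const int dEE = std::max(1, as<int>(net["delay_steps_EE"]));
  const int dEI = std::max(1, as<int>(net["delay_steps_EI"]));
  const int dIE = std::max(1, as<int>(net["delay_steps_IE"]));
  const int dII = std::max(1, as<int>(net["delay_steps_II"]));
  const int B = std::max(std::max(dEE, dEI), std::max(dIE, dII)) + 1;

  // STDP
  const double alphaC = as<double>(net["alpha_C"]);
  const double alphaD = as<double>(net["alpha_D"]);
  const double kC = 1.0 - dt / as<double>(net["tau_C_ms"]);
  const double kD = 1.0 - dt / as<double>(net["tau_D_ms"]);
  const double rho = as<double>(net["rho"]);

  Pop l1e, l1i, l2e, l2i;
  l1e.init(nE, excP);
  l1i.init(nI, inhP);
  l2e.init(nE, excP);
  l2i.init(nI, inhP);

  double sEI1 = 0, sIE1 = 0, sII1 = 0, sEI2 = 0, sIE2 = 0, sII2 = 0;
  std::vector<double> gff(nE, 0.0);
  std::vector<double> C(nE, 0.0), D(nE, 0.0);

  // ring buffers of spike index lists, one per population
  enum { P_L1E = 0, P_L1I, P_L2E, P_L2I, NPOP };
  std::vector<std::vector<std::vector<int> > > buf(
      NPOP, std::vector<std::vector<int> >(B));
  long t = 0;          // global step counter
  long last_reset = 0; // first step with an empty history

  IntegerVector dur_steps = schedule["duration_steps"];
  NumericVector amp_pA = schedule["i_ext_pA"];
  LogicalVector reset_before = schedule["reset_before"];
  List active = schedule["active"]; // 0-based input-E indices per event
  const int nEvents = dur_steps.size();

  Recorder rec;
  std::vector<double> iext(nE, 0.0);

  // spikes emitted at step t - d by population p (empty if pre-reset)
  auto delayed = [&](int p, int d) -> const std::vector<int>& {
    static const std::vector<int> none;
    long src = t - d;
    if (src < last_reset) return none;
    return buf[p][src % B];
  };

  auto do_reset = [&]() {
    l1e.reset(); l1i.reset(); l2e.reset(); l2i.reset();
    sEI1 = sIE1 = sII1 = sEI2 = sIE2 = sII2 = 0.0;
    std::fill(gff.begin(), gff.end(), 0.0);
    std::fill(C.begin(), C.end(), 0.0);
    std::fill(D.begin(), D.end(), 0.0);
    last_reset = t;
  };

  // advance one population; spikes go to its buffer slot and the recorder
  auto stepPop = [&](Pop& P, const double* Isyn, const double* Iadd,
                     bool useNoise, int popId, int layer, int popClass,
                     bool record, int ev) {
    std::vector<int>& slot = buf[popId][t % B];
    slot.clear();
    const PopParams& p = P.par;
    const double a = dt / p.tauM;
    const double ns = p.sigma * std::sqrt(dt / p.tauM);
    const int n = P.size();
    for (int i = 0; i < n; ++i) {
      if (P.refr[i] > 0) {
        --P.refr[i];
        P.V[i] = p.vH;
        continue;
      }
      double I = (Isyn ? Isyn[i] : 0.0) + (Iadd ? Iadd[i] : 0.0);
      double V = P.V[i] + a * (p.v0 - P.V[i] + I / p.g0);
      if (useNoise) V += ns * norm_rand();
      if (!(V > -1e6 && V < 1e6))
        stop("non-finite membrane potential at layer %d neuron %d, t = %g ms",
             layer, i + 1, (double)t * dt);
      if (V >= p.theta) {
        V = p.vH;
        P.refr[i] = p.nRef;
        slot.push_back(i);
        if (record) rec.add((double)t * dt, layer, popClass, i, ev);
      }
      P.V[i] = V;
    }
  };

  std::vector<double> I1e(nE), I1i(nI), I2e(nE), I2i(nI);
  const bool noiseE = noise, noiseI = noise && noise_inh;

  for (int ev = 0; ev < nEvents; ++ev) {
    if (reset_before[ev]) do_reset();
    std::fill(iext.begin(), iext.end(), 0.0);
    IntegerVector act = active[ev];
    for (int k = 0; k < act.size(); ++k) {
      int idx = act[k];
      if (idx < 0 || idx >= nE) stop("active neuron index out of range");
      iext[idx] = amp_pA[ev];
    }
    const int nsteps = dur_steps[ev];

    for (int s = 0; s < nsteps; ++s) {
      // (1) conductances: shared Euler decay, then delayed-spike increments
      sEI1 *= kEI; sIE1 *= kIE; sII1 *= kII;
      sEI2 *= kEI; sIE2 *= kIE; sII2 *= kII;
      for (int i = 0; i < nE; ++i) gff[i] *= kEE;

      const std::vector<int>& ff = delayed(P_L1E, dEE);
      for (size_t u = 0; u < ff.size(); ++u) {
        const double* wrow = &W[0] + ff[u]; // row ff[u], stride nE
        for (int i = 0; i < nE; ++i) gff[i] += lamEE * wrow[(size_t)i * nE];
      }
      sEI1 += incEI * (double)delayed(P_L1E, dEI).size();
      sIE1 += incIE * (double)delayed(P_L1I, dIE).size();
      sII1 += incII * (double)delayed(P_L1I, dII).size();
      sEI2 += incEI * (double)delayed(P_L2E, dEI).size();
      sIE2 += incIE * (double)delayed(P_L2I, dIE).size();
      sII2 += incII * (double)delayed(P_L2I, dII).size();

      // (2) synaptic currents (pA): g * (reversal - V)
      for (int i = 0; i < nE; ++i) I1e[i] = sIE1 * (vhatI - l1e.V[i]);
      for (int i = 0; i < nI; ++i)
        I1i[i] = sEI1 * (vhatE - l1i.V[i]) + sII1 * (vhatI - l1i.V[i]);
      for (int i = 0; i < nE; ++i)
        I2e[i] = gff[i] * (vhatE - l2e.V[i]) + sIE2 * (vhatI - l2e.V[i]);
      for (int i = 0; i < nI; ++i)
        I2i[i] = sEI2 * (vhatE - l2i.V[i]) + sII2 * (vhatI - l2i.V[i]);

      // (3) membranes and spike detection
      stepPop(l1e, I1e.data(), iext.data(), noiseE, P_L1E, 1, 0,
              record_input, ev + 1);
      stepPop(l1i, I1i.data(), nullptr, noiseI, P_L1I, 1, 1,
              record_inh, ev + 1);
      stepPop(l2e, I2e.data(), nullptr, noiseE, P_L2E, 2, 0,
              record_output, ev + 1);
      stepPop(l2i, I2i.data(), nullptr, noiseI, P_L2I, 2, 1,
              record_inh, ev + 1);

      // (4) plasticity: trace decay, trace jumps, then weight updates
      if (learning_on) {
        for (int j = 0; j < nE; ++j) C[j] *= kC;
        for (int i = 0; i < nE; ++i) D[i] *= kD;
        const std::vector<int>& pre = delayed(P_L1E, dEE);
        for (size_t u = 0; u < pre.size(); ++u)
          C[pre[u]] += alphaC * (1.0 - C[pre[u]]);
        const std::vector<int>& post = buf[P_L2E][t % B];
        for (size_t u = 0; u < post.size(); ++u)
          D[post[u]] += alphaD * (1.0 - D[post[u]]);
        // LTP: postsynaptic spike i reads column i of W
        for (size_t u = 0; u < post.size(); ++u) {
          double* wcol = &W[0] + (size_t)post[u] * nE;
          for (int j = 0; j < nE; ++j)
            wcol[j] += rho * (1.0 - wcol[j]) * C[j];
        }
        // LTD: delayed presynaptic spike j reads row j of W
        for (size_t u = 0; u < pre.size(); ++u) {
          double* wrow = &W[0] + pre[u];
          for (int i = 0; i < nE; ++i)
            wrow[(size_t)i * nE] -= rho * wrow[(size_t)i * nE] * D[i];
        }
      }
      ++t;
    }
  }

  return List::create(
      _["time_ms"] = wrap(rec.t), _["layer"] = wrap(rec.layer),
      _["pop"] = wrap(rec.pop), _["neuron"] = wrap(rec.neuron),
      _["event"] = wrap(rec.event), _["weights"] = W,
      _["V_input_exc"] = wrap(l1e.V), _["V_output_exc"] = wrap(l2e.V),
      _["n_steps"] = (double)t);
}
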