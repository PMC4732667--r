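// Fixed-step integrator for networks of multicompartment conductance-based
// neurons with event-driven dual-exponential synapses, gap junctions and
// perfusion-style conductance drives.
//
// Units: V mV, t ms, conductance uS, current nA, capacitance nF.
// Sign convention: outward ionic current positive;
//   C dV/dt = -sum(i_ion) - i_syn + i_inj + i_axial + i_gap.
//
// Scheme: gates by analytic exponential update (tabulated rates), membrane
// voltage implicit in the linear (ohmic + synaptic) terms with axial coupling
// solved per neuron by the Thomas algorithm; gap-junction and GHK currents
// explicit. Synaptic deliveries are snapped to the nearest step boundary.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const double RGAS = 8.314;    // J/(mol K)
static const double FARADAY = 96485; // C/mol

// splitmix64 counter RNG for synaptic transmission draws
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  double unif() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    z = z ^ (z >> 31);
    return (z >> 11) * (1.0 / 9007199254740992.0);
  }
};

// generalised HH rate (A + B*V) / (C + exp((D + V)/E)), removable
// singularities replaced by their L'Hopital limit
static double hh_rate(double A, double B, double C, double D, double E,
                      double V) {
  double den = C + std::exp((D + V) / E);
  double r;
  if (std::fabs(den) < 1e-7) {
    r = -B * E / C; // limit where numerator and denominator vanish together
  } else {
    r = (A + B * V) / den;
  }
  return r > 0.0 ? r : 0.0;
}

struct GateTable {
  // tabulated on a fixed voltage grid for one (gate, dt) pair
  std::vector<double> xinf, decay, decay_half;
};

static const double VGRID_LO = -120.0, VGRID_HI = 80.0, VGRID_STEP = 0.05;

static void build_table(GateTable &tb, const double *a, const double *b,
                        double dt) {
  int n = (int)std::lround((VGRID_HI - VGRID_LO) / VGRID_STEP) + 1;
  tb.xinf.resize(n);
  tb.decay.resize(n);
  tb.decay_half.resize(n);
  for (int i = 0; i < n; i++) {
    double V = VGRID_LO + i * VGRID_STEP;
    double al = hh_rate(a[0], a[1], a[2], a[3], a[4], V);
    double be = hh_rate(b[0], b[1], b[2], b[3], b[4], V);
    double s = al + be;
    tb.xinf[i] = s > 0 ? al / s : 0.0;
    tb.decay[i] = std::exp(-dt * s);
    tb.decay_half[i] = std::exp(-0.5 * dt * s);
  }
}

static inline void table_at(const GateTable &tb, double V, double &xinf,
                            double &decay, double &decay_half) {
  double u = (V - VGRID_LO) / VGRID_STEP;
  int n = (int)tb.xinf.size();
  int i;
  double f;
  if (u <= 0) { i = 0; f = 0.0; }
  else if (u >= n - 1) { i = n - 2; f = 1.0; }
  else { i = (int)u; f = u - i; }
  xinf = tb.xinf[i] + f * (tb.xinf[i + 1] - tb.xinf[i]);
  decay = tb.decay[i] + f * (tb.decay[i + 1] - tb.decay[i]);
  decay_half = tb.decay_half[i] + f * (tb.decay_half[i + 1] - tb.decay_half[i]);
}

// GHK flux current for a divalent ion, returned in nA (outward positive).
// p_area = permeability (cm/s) * membrane area (cm^2); ci, co in mol/cm^3.
static double ghk_current_nA(double p_area, double ci, double co, double Tk,
                             double Vmv) {
  double z = 2.0;
  double Vv = Vmv * 1e-3;
  double u = z * FARADAY * Vv / (RGAS * Tk);
  double flux; // A
  if (std::fabs(u) < 1e-4) {
    // series limit of u*(ci - co*exp(-u))/(1-exp(-u)) as u -> 0
    // (first order in u; relative error O(u^2) at the branch point)
    flux = p_area * z * FARADAY * ((ci - co) + u * (ci + co) / 2.0);
  } else {
    flux = p_area * z * FARADAY * u * (ci - co * std::exp(-u)) /
           (1.0 - std::exp(-u));
  }
  return flux * 1e9; // A -> nA
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(List net, List drive, List cfg) {
  // --- unpack network -------------------------------------------------
  NumericVector cap = net["cap"];
  IntegerVector noff = net["neuron_offset"]; // length nneuron+1, 0-based comps
  NumericVector ax_g = net["ax_g"];          // per-neuron consecutive coupling
  NumericVector v0 = net["v0"];
  int ncomp = cap.size();
  int nneuron = noff.size() - 1;

  IntegerVector ch_comp = net["ch_comp"];
  IntegerVector ch_kind = net["ch_kind"]; // 0 ohmic, 1 ghk
  NumericVector ch_g = net["ch_g"];       // uS (ohmic)
  NumericVector ch_E = net["ch_E"];
  NumericVector ch_parea = net["ch_parea"]; // ghk: perm*area
  NumericVector ch_ci = net["ch_ci"];       // mol/cm^3
  NumericVector ch_co = net["ch_co"];
  NumericVector ch_T = net["ch_T"];
  IntegerVector ch_goff = net["ch_gate_offset"]; // length nchan+1
  int nchan = ch_comp.size();

  IntegerVector gate_exp = net["gate_exp"];
  NumericMatrix gate_rate = net["gate_rate"]; // 10 x ngate
  int ngate = gate_exp.size();

  IntegerVector gj_a = net["gj_a"], gj_b = net["gj_b"];
  NumericVector gj_g = net["gj_g"];
  int ngj = gj_a.size();

  IntegerVector syn_post = net["syn_post"], syn_pre = net["syn_pre"];
  NumericVector syn_tauo = net["syn_tauo"], syn_tauc = net["syn_tauc"];
  NumericVector syn_g = net["syn_g"], syn_E = net["syn_E"];
  NumericVector syn_mgc = net["syn_mgc"], syn_gamma = net["syn_gamma"];
  NumericVector syn_norm = net["syn_norm"], syn_delay = net["syn_delay"];
  NumericVector syn_p = net["syn_p"];
  IntegerVector syn_nmda = net["syn_nmda"]; // tag for conductance recording
  int nsyn = syn_post.size();

  IntegerVector pf_comp = net["perf_comp"];
  NumericVector pf_g = net["perf_g"], pf_on = net["perf_onset"];
  NumericVector pf_tauo = net["perf_tauo"], pf_tauc = net["perf_tauc"];
  NumericVector pf_norm = net["perf_norm"], pf_mgc = net["perf_mgc"];
  NumericVector pf_gamma = net["perf_gamma"], pf_E = net["perf_E"];
  int nperf = pf_comp.size();

  IntegerVector inj_comp = net["inj_comp"];
  NumericVector inj_amp = net["inj_amp"], inj_t0 = net["inj_t0"],
                inj_t1 = net["inj_t1"];
  int ninj = inj_comp.size();

  // --- config ---------------------------------------------------------
  double dt = as<double>(cfg["dt"]);
  double duration = as<double>(cfg["duration"]);
  uint64_t seed = (uint64_t)as<double>(cfg["seed"]);
  int record_every = as<int>(cfg["record_every"]);
  bool record_g = as<bool>(cfg["record_g"]);
  double thr = as<double>(cfg["spike_threshold"]);
  double reset = as<double>(cfg["spike_reset"]);
  IntegerVector rec_comps = cfg["record_comps"]; // extra compartments, 0-based
  double theta = as<double>(cfg["theta"]); // 0.5 trapezoidal .. 1 implicit
  long nstep = (long)std::lround(duration / dt);

  // --- tables and state -----------------------------------------------
  // deduplicate gate rate tables: many compartments share identical kinetics
  std::vector<GateTable> tables;
  std::vector<int> gate_tab(ngate);
  {
    std::vector<int> reps; // gate index representative per table
    for (int g = 0; g < ngate; g++) {
      int found = -1;
      for (size_t u = 0; u < reps.size(); u++) {
        bool same = true;
        for (int k = 0; k < 10 && same; k++)
          if (gate_rate(k, reps[u]) != gate_rate(k, g)) same = false;
        if (same) { found = (int)u; break; }
      }
      if (found < 0) {
        double a[5], b[5];
        for (int k = 0; k < 5; k++) {
          a[k] = gate_rate(k, g);
          b[k] = gate_rate(5 + k, g);
        }
        tables.push_back(GateTable());
        build_table(tables.back(), a, b, dt);
        reps.push_back(g);
        found = (int)tables.size() - 1;
      }
      gate_tab[g] = found;
    }
  }

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> Vprev(v0.begin(), v0.end());
  std::vector<double> X(ngate);
  for (int c = 0; c < nchan; c++) {
    double Vm = V[ch_comp[c]];
    for (int g = ch_goff[c]; g < ch_goff[c + 1]; g++) {
      double a[5], b[5];
      for (int k = 0; k < 5; k++) { a[k] = gate_rate(k, g); b[k] = gate_rate(5 + k, g); }
      double al = hh_rate(a[0], a[1], a[2], a[3], a[4], Vm);
      double be = hh_rate(b[0], b[1], b[2], b[3], b[4], Vm);
      X[g] = (al + be) > 0 ? al / (al + be) : 0.0;
    }
  }

  std::vector<double> A(nsyn, 0.0), B(nsyn, 0.0);
  std::vector<double> dA(nsyn), dB(nsyn), dAh(nsyn), dBh(nsyn);
  for (int s = 0; s < nsyn; s++) {
    dA[s] = std::exp(-dt / syn_tauo[s]);
    dB[s] = std::exp(-dt / syn_tauc[s]);
    dAh[s] = std::exp(-0.5 * dt / syn_tauo[s]);
    dBh[s] = std::exp(-0.5 * dt / syn_tauc[s]);
  }

  // event queue: per-step buckets of synapse indices
  std::vector<std::vector<int> > queue((size_t)nstep + 2);
  NumericVector ev_time = drive["ev_time"];
  IntegerVector ev_syn = drive["ev_syn"];
  for (int e = 0; e < ev_syn.size(); e++) {
    long st = (long)std::lround(ev_time[e] / dt);
    if (st >= 0 && st <= nstep) queue[st].push_back(ev_syn[e]);
  }

  // outgoing synapse lists per neuron
  std::vector<std::vector<int> > outgoing(nneuron);
  for (int s = 0; s < nsyn; s++)
    if (syn_pre[s] >= 0) outgoing[syn_pre[s]].push_back(s);

  SplitMix rng(seed * 0x9E3779B97F4A7C15ULL + 0x123456789ULL);

  // recording
  int nsample = (int)(nstep / record_every) + 1;
  int nxtra = rec_comps.size();
  NumericMatrix xrec(nxtra ? nsample : 1, nxtra ? nxtra : 1);
  NumericMatrix vrec(nsample, nneuron);
  NumericMatrix grec(record_g ? nsample : 1, record_g ? nneuron : 1);
  NumericVector trec(nsample);
  std::vector<std::vector<double> > spikes(nneuron);
  std::vector<double> del_time;
  std::vector<int> del_syn;
  std::vector<bool> armed(nneuron, true);
  std::vector<double> soma_prev(nneuron);
  for (int n = 0; n < nneuron; n++) soma_prev[n] = V[noff[n]];

  std::vector<double> gtot(ncomp), gimp(ncomp), rhs(ncomp);
  std::vector<double> gj_rhs(ncomp), gj_rhs_zero(ncomp, 0.0);
  std::vector<double> Vnew_buf(ncomp);
  std::vector<double> cc(ncomp), dd(ncomp); // Thomas scratch

  int isample = 0;
  for (int n = 0; n < nneuron; n++) vrec(0, n) = V[noff[n]];
  for (int x = 0; x < nxtra; x++) xrec(0, x) = V[rec_comps[x]];
  trec[0] = 0.0;
  if (record_g) for (int n = 0; n < nneuron; n++) grec(0, n) = 0.0;
  isample = 1;

  for (long step = 0; step < nstep; step++) {
    double t = step * dt;       // state currently at t
    double tnew = t + dt;

    // deliver events scheduled for this step boundary
    for (size_t k = 0; k < queue[step].size(); k++) {
      int s = queue[step][k];
      A[s] += 1.0;
      B[s] += 1.0;
      del_syn.push_back(s);
      del_time.push_back(t);
    }

    std::fill(gtot.begin(), gtot.end(), 0.0);
    std::fill(gimp.begin(), gimp.end(), 0.0);
    std::fill(rhs.begin(), rhs.end(), 0.0);

    // theta-scheme (trapezoidal for theta = 0.5): every conductance g with
    // driving potential E contributes -g*(theta*V' + (1-theta)*V - E);
    // conductances are evaluated at the midpoint t + dt/2 (staggered gates,
    // half-decayed synaptic states), nonlinear factors (Mg block, GHK) at
    // the extrapolated midpoint voltage.

    // channels: staggered gate update; midpoint state sets the conductance
    for (int c = 0; c < nchan; c++) {
      int cp = ch_comp[c];
      double Vm = V[cp];
      double Vx = 1.5 * V[cp] - 0.5 * Vprev[cp]; // midpoint extrapolation
      double open = 1.0;
      // staggered gates: X lives at half steps (t - dt/2); a full advance
      // with rates at V(t) is centred, and the new X is the midpoint state
      // for the voltage step t -> t + dt
      for (int g = ch_goff[c]; g < ch_goff[c + 1]; g++) {
        double xinf, decay, decay_half;
        table_at(tables[gate_tab[g]], Vm, xinf, decay, decay_half);
        double x = xinf + (X[g] - xinf) * decay;
        X[g] = x;
        for (int e = 0; e < gate_exp[g]; e++) open *= x;
      }
      if (ch_kind[c] == 0) {
        double gch = ch_g[c] * open;
        gtot[cp] += gch;
        rhs[cp] += gch * ch_E[c];
      } else {
        double ighk = ghk_current_nA(ch_parea[c] * open, ch_ci[c], ch_co[c],
                                     ch_T[c], Vx);
        rhs[cp] -= ighk; // outward positive -> subtract
      }
    }

    // synapses (midpoint conductance; events were delivered above at t)
    for (int s = 0; s < nsyn; s++) {
      double gs = syn_g[s] * (B[s] * dBh[s] - A[s] * dAh[s]) / syn_norm[s];
      A[s] *= dA[s];
      B[s] *= dB[s];
      if (gs <= 0) continue;
      int cp = syn_post[s];
      double geff = gs;
      if (syn_mgc[s] > 0) {
        double Vx = 1.5 * V[cp] - 0.5 * Vprev[cp];
        geff = gs / (1.0 + syn_mgc[s] * std::exp(-syn_gamma[s] * Vx));
      }
      gtot[cp] += geff;
      rhs[cp] += geff * syn_E[s];
    }

    // perfusion drives (midpoint)
    for (int p = 0; p < nperf; p++) {
      double ts = t + 0.5 * dt - pf_on[p];
      if (ts <= 0) continue;
      double gs = pf_g[p] *
                  (std::exp(-ts / pf_tauc[p]) - std::exp(-ts / pf_tauo[p])) /
                  pf_norm[p];
      if (gs <= 0) continue;
      int cp = pf_comp[p];
      double geff = gs;
      if (pf_mgc[p] > 0) {
        double Vx = 1.5 * V[cp] - 0.5 * Vprev[cp];
        geff = gs / (1.0 + pf_mgc[p] * std::exp(-pf_gamma[p] * Vx));
      }
      gtot[cp] += geff;
      rhs[cp] += geff * pf_E[p];
    }

    // injected currents
    for (int j = 0; j < ninj; j++)
      if (t >= inj_t0[j] && t < inj_t1[j]) rhs[inj_comp[j]] += inj_amp[j];

    // Gap junctions couple different neurons, outside the per-neuron
    // tridiagonal solve. Predictor: own endpoint fully implicit, partner
    // at time t (unconditionally stable even when many junctions converge
    // on one small compartment). Corrector: trapezoidal with the partner
    // taken at the predicted midpoint, restoring second-order accuracy.
    auto solve_pass = [&](const std::vector<double> &gj_diag_extra,
                          const std::vector<double> &gj_rhs,
                          std::vector<double> &Vout) {
      int axbase = 0;
      for (int n = 0; n < nneuron; n++) {
        int lo = noff[n], hi = noff[n + 1]; // comps [lo, hi)
        int k = hi - lo;
        for (int i = 0; i < k; i++) {
          int cp = lo + i;
          double diag =
              cap[cp] / dt + theta * gtot[cp] + gj_diag_extra[cp];
          double r = cap[cp] / dt * V[cp] + rhs[cp] + gj_rhs[cp] -
                     (1.0 - theta) * gtot[cp] * V[cp];
          if (i > 0) {
            diag += theta * ax_g[axbase + i - 1];
            r += ax_g[axbase + i - 1] *
                 ((1.0 - theta) * (V[cp - 1] - V[cp]));
          }
          if (i < k - 1) {
            diag += theta * ax_g[axbase + i];
            r += ax_g[axbase + i] * ((1.0 - theta) * (V[cp + 1] - V[cp]));
          }
          cc[cp] = diag;
          dd[cp] = r;
        }
        for (int i = 1; i < k; i++) { // forward sweep, off-diag -theta*ax
          int cp = lo + i;
          double off = -theta * ax_g[axbase + i - 1];
          double w = off / cc[cp - 1];
          cc[cp] -= w * off;
          dd[cp] -= w * dd[cp - 1];
        }
        Vout[hi - 1] = dd[hi - 1] / cc[hi - 1];
        for (int i = k - 2; i >= 0; i--) {
          int cp = lo + i;
          Vout[cp] = (dd[cp] + theta * ax_g[axbase + i] * Vout[cp + 1]) /
                     cc[cp];
        }
        axbase += k - 1;
      }
    };

    std::vector<double> &Vnew = Vnew_buf;
    if (ngj == 0) {
      std::fill(gimp.begin(), gimp.end(), 0.0);
      solve_pass(gimp, gj_rhs_zero, Vnew);
    } else {
      // predictor
      std::fill(gimp.begin(), gimp.end(), 0.0);
      std::fill(gj_rhs.begin(), gj_rhs.end(), 0.0);
      for (int j = 0; j < ngj; j++) {
        int a = gj_a[j], b = gj_b[j];
        gimp[a] += gj_g[j];
        gj_rhs[a] += gj_g[j] * V[b];
        gimp[b] += gj_g[j];
        gj_rhs[b] += gj_g[j] * V[a];
      }
      solve_pass(gimp, gj_rhs, Vnew);
      // corrector, iterated to the coupled trapezoidal fixed point:
      // i_gj = g * (Vmid_partner - (V + V')/2)
      for (int it = 0; it < 4; it++) {
        std::fill(gimp.begin(), gimp.end(), 0.0);
        std::fill(gj_rhs.begin(), gj_rhs.end(), 0.0);
        for (int j = 0; j < ngj; j++) {
          int a = gj_a[j], b = gj_b[j];
          double mb = 0.5 * (V[b] + Vnew[b]);
          double ma = 0.5 * (V[a] + Vnew[a]);
          gimp[a] += 0.5 * gj_g[j];
          gj_rhs[a] += gj_g[j] * (mb - 0.5 * V[a]);
          gimp[b] += 0.5 * gj_g[j];
          gj_rhs[b] += gj_g[j] * (ma - 0.5 * V[b]);
        }
        solve_pass(gimp, gj_rhs, Vnew);
      }
    }
    for (int cp = 0; cp < ncomp; cp++) {
      Vprev[cp] = V[cp];
      V[cp] = Vnew[cp];
    }

    // blow-up guard
    for (int n = 0; n < nneuron; n++) {
      double v = V[noff[n]];
      if (!std::isfinite(v) || std::fabs(v) > 200.0)
        stop("numerical blow-up: |V| > 200 mV at t = %f ms (neuron %d)", tnew,
             n + 1);
    }

    // spike detection on somata + synaptic event generation
    for (int n = 0; n < nneuron; n++) {
      double vold = soma_prev[n], vnew = V[noff[n]];
      if (armed[n] && vold < thr && vnew >= thr) {
        double tc = t + dt * (thr - vold) / (vnew - vold);
        spikes[n].push_back(tc);
        armed[n] = false;
        for (size_t k2 = 0; k2 < outgoing[n].size(); k2++) {
          int s = outgoing[n][k2];
          if (syn_p[s] >= 1.0 || rng.unif() < syn_p[s]) {
            long st = (long)std::lround((tc + syn_delay[s]) / dt);
            if (st >= 0 && st <= nstep) queue[st].push_back(s);
          }
        }
      } else if (!armed[n] && vnew < reset) {
        armed[n] = true;
      }
      soma_prev[n] = vnew;
    }

    // record
    if ((step + 1) % record_every == 0 && isample < nsample) {
      trec[isample] = tnew;
      for (int n = 0; n < nneuron; n++) vrec(isample, n) = V[noff[n]];
      for (int x = 0; x < nxtra; x++) xrec(isample, x) = V[rec_comps[x]];
      if (record_g) {
        // raw (pre-Mg-block) conductance of NMDA-tagged synapses and
        // perfusion drives, summed per postsynaptic neuron
        std::vector<double> gn(nneuron, 0.0);
        for (int s = 0; s < nsyn; s++) {
          double gs = syn_g[s] * (B[s] - A[s]) / syn_norm[s];
          if (gs < 0) gs = 0;
          // neuron owning compartment syn_post[s]
          if (!syn_nmda[s]) continue;
          int cp = syn_post[s];
          int nn = 0;
          while (noff[nn + 1] <= cp) nn++;
          gn[nn] += gs;
        }
        for (int p = 0; p < nperf; p++) {
          double ts = tnew - pf_on[p];
          if (ts <= 0) continue;
          double gs = pf_g[p] *
                      (std::exp(-ts / pf_tauc[p]) - std::exp(-ts / pf_tauo[p])) /
                      pf_norm[p];
          if (gs < 0) continue;
          int cp = pf_comp[p];
          int nn = 0;
          while (noff[nn + 1] <= cp) nn++;
          gn[nn] += gs;
        }
        for (int n = 0; n < nneuron; n++) grec(isample, n) = gn[n];
      }
      isample++;
    }
  }

  List spk(nneuron);
  for (int n = 0; n < nneuron; n++) spk[n] = wrap(spikes[n]);
  return List::create(
      _["time"] = trec, _["v"] = vrec,
      _["g_nmda"] = record_g ? (SEXP)grec : R_NilValue, _["spikes"] = spk,
      _["v_extra"] = nxtra ? (SEXP)xrec : R_NilValue,
      _["delivery_syn"] = wrap(del_syn), _["delivery_time"] = wrap(del_time),
      _["v_final"] = wrap(V));
}

// [[Rcpp::export(name = ".gate_rate_cpp")]]
NumericVector gate_rate_cpp(NumericVector coef, NumericVector V) {
  NumericVector out(V.size());
  for (int i = 0; i < V.size(); i++)
    out[i] = hh_rate(coef[0], coef[1], coef[2], coef[3], coef[4], V[i]);
  return out;
}

// [[Rcpp::export(name = ".ghk_current_cpp")]]
NumericVector ghk_current_cpp(double p_area, double ci, double co, double Tk,
                              NumericVector V) {
  NumericVector out(V.size());
  for (int i = 0; i < V.size(); i++)
    out[i] = ghk_current_nA(p_area, ci, co, Tk, V[i]);
  return out;
}
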