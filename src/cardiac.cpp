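#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Six-compartment closed-loop circulation: LV, systemic arteries (sa),
// systemic veins (sv), RV, pulmonary arteries (pa), pulmonary veins (pv).
// Ventricles follow a time-varying elastance; valves are ideal diodes.
// State = compartment volumes (mL); pressures derived algebraically.
//
// Parameter vector layout (see R/cardiac.R):
//  0 T      cycle length (s)        1 Tsys  systolic duration (s)
//  2 EdLV   3 EsLV   4 EdRV   5 EsRV          (mmHg/mL)
//  6 Esa    7 Esv    8 Epa    9 Epv           (mmHg/mL)
// 10..15 unstressed volumes V0 (lv, sa, sv, rv, pa, pv) (mL)
// 16 Rmv  17 Rav  18 Rtv  19 Rpuv             valve resistances (mmHg s/mL)
// 20 SVR  21 PVR                              (mmHg s/mL)

struct CircPars {
  double T, Tsys, EdLV, EsLV, EdRV, EsRV, Esa, Esv, Epa, Epv;
  double V0[6];
  double Rmv, Rav, Rtv, Rpuv, SVR, PVR;
};

static inline double activation(double t, const CircPars &p) {
  if (t >= p.Tsys) return 0.0;
  return 0.5 * (1.0 - std::cos(2.0 * M_PI * t / p.Tsys));
}

// the within-cycle activation waveform is the same every beat: precompute it
// on the RK4 sub-grid (t, t+h/2, t+h per step)
struct ActTable {
  std::vector<double> a0, ah, a1;
  void build(int nStep, double h, const CircPars &p) {
    a0.resize(nStep); ah.resize(nStep); a1.resize(nStep);
    for (int s = 0; s < nStep; ++s) {
      double t = s * h;
      a0[s] = activation(t, p);
      ah[s] = activation(t + 0.5 * h, p);
      a1[s] = activation(t + h, p);
    }
  }
};

// v: 0 lv, 1 sa, 2 sv, 3 rv, 4 pa, 5 pv
static inline void pressures(const double *v, double a, const CircPars &p,
                             double *P) {
  double Elv = p.EdLV + (p.EsLV - p.EdLV) * a;
  double Erv = p.EdRV + (p.EsRV - p.EdRV) * a;
  P[0] = Elv * (v[0] - p.V0[0]);
  P[1] = p.Esa * (v[1] - p.V0[1]);
  P[2] = p.Esv * (v[2] - p.V0[2]);
  P[3] = Erv * (v[3] - p.V0[3]);
  P[4] = p.Epa * (v[4] - p.V0[4]);
  P[5] = p.Epv * (v[5] - p.V0[5]);
}

static inline void deriv(double a, const double *v, double *dv,
                         const CircPars &p) {
  double P[6];
  pressures(v, a, p, P);
  double Qmv  = P[5] > P[0] ? (P[5] - P[0]) / p.Rmv  : 0.0;
  double Qav  = P[0] > P[1] ? (P[0] - P[1]) / p.Rav  : 0.0;
  double Qsys = (P[1] - P[2]) / p.SVR;
  double Qtv  = P[2] > P[3] ? (P[2] - P[3]) / p.Rtv  : 0.0;
  double Qpuv = P[3] > P[4] ? (P[3] - P[4]) / p.Rpuv : 0.0;
  double Qpul = (P[4] - P[5]) / p.PVR;
  dv[0] = Qmv - Qav;
  dv[1] = Qav - Qsys;
  dv[2] = Qsys - Qtv;
  dv[3] = Qtv - Qpuv;
  dv[4] = Qpuv - Qpul;
  dv[5] = Qpul - Qmv;
}

static inline void rk4_step(double a0, double ah, double a1, double *v,
                            double h, const CircPars &p) {
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  deriv(a0, v, k1, p);
  for (int i = 0; i < 6; ++i) tmp[i] = v[i] + 0.5 * h * k1[i];
  deriv(ah, tmp, k2, p);
  for (int i = 0; i < 6; ++i) tmp[i] = v[i] + 0.5 * h * k2[i];
  deriv(ah, tmp, k3, p);
  for (int i = 0; i < 6; ++i) tmp[i] = v[i] + h * k3[i];
  deriv(a1, tmp, k4, p);
  for (int i = 0; i < 6; ++i)
    v[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// [[Rcpp::export(name = ".cardiacRunCpp")]]
List cardiacRunCpp(NumericVector init, NumericVector pars, double dt,
                   int maxCycles, double tol, int nSamples) {
  CircPars p;
  p.T = pars[0]; p.Tsys = pars[1];
  p.EdLV = pars[2]; p.EsLV = pars[3]; p.EdRV = pars[4]; p.EsRV = pars[5];
  p.Esa = pars[6]; p.Esv = pars[7]; p.Epa = pars[8]; p.Epv = pars[9];
  for (int i = 0; i < 6; ++i) p.V0[i] = pars[10 + i];
  p.Rmv = pars[16]; p.Rav = pars[17]; p.Rtv = pars[18]; p.Rpuv = pars[19];
  p.SVR = pars[20]; p.PVR = pars[21];

  double v[6];
  for (int i = 0; i < 6; ++i) v[i] = init[i];

  int nStep = (int)std::ceil(p.T / dt);
  double h = p.T / nStep;
  ActTable act;
  act.build(nStep, h, p);

  double prev[4] = {0, 0, 0, 0};  // SBP, DBP, SV(LV), SV(RV)
  bool converged = false;
  int cycle = 0;

  // per-cycle accumulators (refreshed each cycle; last cycle reported)
  double SBP = 0, DBP = 0, MAPint = 0, LVEDV = 0, LVESV = 0, LVPSP = 0,
         LVEDP = 0, RVEDV = 0, RVESV = 0, RVPSP = 0, RVEDP = 0, PAPs = 0,
         PAPd = 0, Qsysint = 0, Psvint = 0, Ppvint = 0;

  NumericMatrix samples(nSamples > 0 ? nSamples : 1, 9);
  CharacterVector sampCols = CharacterVector::create(
      "t", "P_lv", "P_sa", "P_sv", "P_rv", "P_pa", "P_pv", "V_lv", "V_rv");

  for (cycle = 0; cycle < maxCycles && !converged; ++cycle) {
    double P[6];
    pressures(v, activation(0.0, p), p, P);
    SBP = P[1]; DBP = P[1]; MAPint = 0;
    LVEDV = v[0]; LVESV = v[0]; LVPSP = P[0]; LVEDP = P[0];
    RVEDV = v[3]; RVESV = v[3]; RVPSP = P[3]; RVEDP = P[3];
    PAPs = P[4]; PAPd = P[4]; Qsysint = 0; Psvint = 0; Ppvint = 0;
    int sampEvery = nSamples > 0 ? std::max(1, nStep / nSamples) : 0;
    int sampIdx = 0;

    for (int s = 0; s < nStep; ++s) {
      double t = s * h;
      rk4_step(act.a0[s], act.ah[s], act.a1[s], v, h, p);
      pressures(v, act.a1[s], p, P);
      if (P[1] > SBP) SBP = P[1];
      if (P[1] < DBP) DBP = P[1];
      MAPint += P[1] * h;
      Psvint += P[2] * h;
      Ppvint += P[5] * h;
      Qsysint += (P[1] - P[2]) / p.SVR * h;
      if (v[0] > LVEDV) LVEDV = v[0];
      if (v[0] < LVESV) LVESV = v[0];
      if (P[0] > LVPSP) LVPSP = P[0];
      if (v[3] > RVEDV) RVEDV = v[3];
      if (v[3] < RVESV) RVESV = v[3];
      if (P[3] > RVPSP) RVPSP = P[3];
      if (P[4] > PAPs) PAPs = P[4];
      if (P[4] < PAPd) PAPd = P[4];
      if (nSamples > 0 && sampEvery > 0 && s % sampEvery == 0 &&
          sampIdx < nSamples) {
        samples(sampIdx, 0) = t + h;
        samples(sampIdx, 1) = P[0];
        samples(sampIdx, 2) = P[1];
        samples(sampIdx, 3) = P[2];
        samples(sampIdx, 4) = P[3];
        samples(sampIdx, 5) = P[4];
        samples(sampIdx, 6) = P[5];
        samples(sampIdx, 7) = v[0];
        samples(sampIdx, 8) = v[3];
        ++sampIdx;
      }
    }

    double cur[4] = {SBP, DBP, LVEDV - LVESV, RVEDV - RVESV};
    if (cycle > 0) {
      double rel = 0;
      for (int i = 0; i < 4; ++i) {
        double d = std::fabs(cur[i] - prev[i]) /
                   std::max(1.0, std::fabs(prev[i]));
        if (d > rel) rel = d;
      }
      if (rel < tol) converged = true;
    }
    for (int i = 0; i < 4; ++i) prev[i] = cur[i];
  }

  double SV = LVEDV - LVESV;
  NumericVector summary = NumericVector::create(
      _["SBP"] = SBP, _["DBP"] = DBP, _["MAP"] = MAPint / p.T,
      _["HR"] = 60.0 / p.T, _["SV"] = SV, _["EDV"] = LVEDV, _["ESV"] = LVESV,
      _["EF"] = LVEDV > 0 ? 100.0 * SV / LVEDV : NA_REAL,
      _["CO"] = SV / p.T, _["LVEDP"] = LVEDP, _["LVPSP"] = LVPSP,
      _["RVEDP"] = RVEDP, _["RVPSP"] = RVPSP, _["RVEDV"] = RVEDV,
      _["RVESV"] = RVESV, _["PAPsys"] = PAPs, _["PAPdia"] = PAPd,
      _["P_sv"] = Psvint / p.T, _["P_pv"] = Ppvint / p.T);

  colnames(samples) = sampCols;
  return List::create(_["summary"] = summary,
                      _["volumes"] = NumericVector(v, v + 6),
                      _["cycles"] = cycle, _["converged"] = converged,
                      _["samples"] = samples);
}
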