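// ten Tusscher - Noble - Noble - Panfilov (2004) human ventricular
// epicardial cell model (the original "TNNP" model), CellML-distributed
// parameterization, with scalable maximal conductances for IKs, IKr and IK1.
// Mirrors the structure of tnnp.cpp (exact path + lookup-table pacing path).
// Key structural differences from the 2006 revision: single cytosolic Ca
// compartment (no subspace), L-type current gated by d*f*fCa with
// calcium-dependent fCa, SR release gated by d*g with the calcium-dependent
// g gate, and the fCa/g "no reactivation while depolarized" update rule.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace tnnp04 {

static const double Rgas = 8314.472;
static const double Temp = 310.0;
static const double Frdy = 96485.3415;
static const double RTF  = Rgas * Temp / Frdy;

static const double Ko  = 5.4;
static const double Nao = 140.0;
static const double Cao = 2.0;

static const double Gna   = 14.838;
static const double GcaL  = 1.75e-4;
static const double Gto   = 0.294;    // epi
static const double Gkr   = 0.096;
static const double Gks   = 0.245;    // epi
static const double Gk1   = 5.405;
static const double GpCa  = 0.825;
static const double GpK   = 0.0146;
static const double GbNa  = 0.00029;
static const double GbCa  = 0.000592;

static const double pKNa  = 0.03;
static const double Pnak  = 1.362;
static const double KmK   = 1.0;
static const double KmNa  = 40.0;
static const double knaca = 1000.0;
static const double KmNai = 87.5;
static const double KmCa  = 1.38;
static const double ksat  = 0.1;
static const double nalph = 2.5;
static const double gam   = 0.35;
static const double KpCa  = 0.0005;

static const double Cm  = 0.185;
static const double Vc  = 0.016404;
static const double Vsr = 0.001094;

static const double Bufc  = 0.15, Kbufc  = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Vmaxup = 0.000425, Kup = 0.00025;
static const double Vleak  = 8e-5;
static const double arel = 0.016464, brel = 0.25, crel = 0.008232;

enum { iV = 0, iNai, iKi, iCai, iCasr, ifca, ig,
       im, ih, ij, id_, if_, ir, is_, ixr1, ixr2, ixs, NSTATE };

static const char *STATE_NAMES[NSTATE] = {
  "Vm", "Nai", "Ki", "Cai", "Casr", "fCa", "g",
  "m", "h", "j", "d", "f", "r", "s", "xr1", "xr2", "xs" };

// published initial conditions (CellML 2004 epicardial)
static const double INIT_STATE[NSTATE] = {
  -86.2,    // Vm
  11.6,     // Nai
  138.3,    // Ki
  0.0002,   // Cai
  0.2,      // Casr
  1.0,      // fCa
  1.0,      // g
  0.0,      // m
  0.75,     // h
  0.75,     // j
  0.0,      // d
  1.0,      // f
  0.0,      // r
  1.0,      // s
  0.0,      // xr1
  1.0,      // xr2
  0.0       // xs
};

enum { GM = 0, GH, GJ, GD, GF, GR, GS, GXR1, GXR2, GXS, NGATE };
static const int GATE_STATE[NGATE] = { im, ih, ij, id_, if_, ir, is_, ixr1, ixr2, ixs };

static void gate_inf_tau(double V, double *inf, double *tau) {
  inf[GM] = 1.0 / pow(1.0 + exp((-56.86 - V) / 9.03), 2.0);
  {
    double am = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
    double bm = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) + 0.1 / (1.0 + exp((V - 50.0) / 200.0));
    tau[GM] = am * bm;
  }
  inf[GH] = 1.0 / pow(1.0 + exp((V + 71.55) / 7.43), 2.0);
  {
    double ah, bh;
    if (V >= -40.0) { ah = 0.0; bh = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1))); }
    else { ah = 0.057 * exp(-(V + 80.0) / 6.8);
           bh = 2.7 * exp(0.079 * V) + 310000.0 * exp(0.3485 * V); }
    tau[GH] = 1.0 / (ah + bh);
  }
  inf[GJ] = inf[GH];
  {
    double aj, bj;
    if (V >= -40.0) { aj = 0.0;
      bj = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0))); }
    else {
      aj = (-25428.0 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) * (V + 37.78) /
           (1.0 + exp(0.311 * (V + 79.23)));
      bj = 0.02424 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
    }
    tau[GJ] = 1.0 / (aj + bj);
  }
  // 2004 d gate: half-activation at -5 mV
  inf[GD] = 1.0 / (1.0 + exp((-5.0 - V) / 7.5));
  {
    double ad = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
    double bd = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
    double gd = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
    tau[GD] = ad * bd + gd;
  }
  inf[GF] = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
  tau[GF] = 1125.0 * exp(-pow(V + 27.0, 2.0) / 240.0) + 80.0 +
            165.0 / (1.0 + exp((25.0 - V) / 10.0));
  inf[GR] = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
  tau[GR] = 9.5 * exp(-pow(V + 40.0, 2.0) / 1800.0) + 0.8;
  inf[GS] = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
  tau[GS] = 85.0 * exp(-pow(V + 45.0, 2.0) / 320.0) +
            5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;
  inf[GXR1] = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
  {
    double a = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
    double b = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
    tau[GXR1] = a * b;
  }
  inf[GXR2] = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
  {
    double a = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
    double b = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
    tau[GXR2] = a * b;
  }
  inf[GXS] = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
  {
    double a = 1100.0 / sqrt(1.0 + exp((-10.0 - V) / 6.0));
    double b = 1.0 / (1.0 + exp((V - 60.0) / 20.0));
    tau[GXS] = a * b;
  }
}

static void fca_inf(double Cai, double &inf) {
  double a = 1.0 / (1.0 + pow(Cai / 0.000325, 8.0));
  double b = 0.1 / (1.0 + exp((Cai - 0.0005) / 0.0001));
  double c = 0.2 / (1.0 + exp((Cai - 0.00075) / 0.0008));
  inf = (a + b + c + 0.23) / 1.46;
}

static void g_inf(double Cai, double &inf) {
  if (Cai <= 0.00035) inf = 1.0 / (1.0 + pow(Cai / 0.00035, 6.0));
  else                inf = 1.0 / (1.0 + pow(Cai / 0.00035, 16.0));
}
static const double TAU_FCA = 2.0, TAU_G = 2.0;

struct Currents {
  double INa, ICaL, Ito, IKr, IKs, IK1, INaCa, INaK, IpCa, IpK, IbNa, IbCa, Iion;
};

static inline double zexpm1(double z) {
  if (fabs(z) < 1e-6) return 1.0 - z / 2.0 + z * z / 12.0;
  return z / expm1(z);
}

static void compute_currents(const double *s, double sKs, double sKr, double sK1,
                             Currents &c) {
  double V = s[iV];
  double ENa = RTF * log(Nao / s[iNai]);
  double EK  = RTF * log(Ko / s[iKi]);
  double EKs = RTF * log((Ko + pKNa * Nao) / (s[iKi] + pKNa * s[iNai]));
  double ECa = 0.5 * RTF * log(Cao / s[iCai]);

  c.INa = Gna * pow(s[im], 3.0) * s[ih] * s[ij] * (V - ENa);

  double z = 2.0 * V / RTF;
  double q = zexpm1(z);
  // ICaL = GcaL*d*f*fCa * 2F * q * (Cai*e^z - 0.341*Cao)
  c.ICaL = GcaL * s[id_] * s[if_] * s[ifca] * 2.0 * Frdy * q *
           (s[iCai] * exp(z) - 0.341 * Cao);

  c.Ito = Gto * s[ir] * s[is_] * (V - EK);
  c.IKr = sKr * Gkr * sqrt(Ko / 5.4) * s[ixr1] * s[ixr2] * (V - EK);
  c.IKs = sKs * Gks * s[ixs] * s[ixs] * (V - EKs);

  double ak1 = 0.1 / (1.0 + exp(0.06 * (V - EK - 200.0)));
  double bk1 = (3.0 * exp(0.0002 * (V - EK + 100.0)) + exp(0.1 * (V - EK - 10.0))) /
               (1.0 + exp(-0.5 * (V - EK)));
  c.IK1 = sK1 * Gk1 * sqrt(Ko / 5.4) * ak1 / (ak1 + bk1) * (V - EK);

  double e1 = exp(gam * V / RTF);
  double e2 = exp((gam - 1.0) * V / RTF);
  c.INaCa = knaca *
      (e1 * pow(s[iNai], 3.0) * Cao - e2 * pow(Nao, 3.0) * s[iCai] * nalph) /
      ((pow(KmNai, 3.0) + pow(Nao, 3.0)) * (KmCa + Cao) * (1.0 + ksat * e2));

  c.INaK = Pnak * Ko * s[iNai] /
      ((Ko + KmK) * (s[iNai] + KmNa) *
       (1.0 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF)));

  c.IpCa = GpCa * s[iCai] / (s[iCai] + KpCa);
  c.IpK  = GpK * (V - EK) / (1.0 + exp((25.0 - V) / 5.98));
  c.IbNa = GbNa * (V - ENa);
  c.IbCa = GbCa * (V - ECa);

  c.Iion = c.INa + c.ICaL + c.Ito + c.IKr + c.IKs + c.IK1 + c.INaCa + c.INaK +
           c.IpCa + c.IpK + c.IbNa + c.IbCa;
}

static void compute_derivs(const double *s, double sKs, double sKr, double sK1,
                           double istim, double *ds) {
  Currents c;
  compute_currents(s, sKs, sKr, sK1, c);
  double V = s[iV];

  ds[iV] = -(c.Iion + istim);

  double Ileak = Vleak * (s[iCasr] - s[iCai]);
  double Iup   = Vmaxup / (1.0 + pow(Kup / s[iCai], 2.0));
  double Irel  = (arel * s[iCasr] * s[iCasr] / (brel * brel + s[iCasr] * s[iCasr]) +
                  crel) * s[id_] * s[ig];

  double bufc = 1.0 / (1.0 + Bufc * Kbufc / pow(s[iCai] + Kbufc, 2.0));
  ds[iCai] = bufc * (Ileak - Iup + Irel -
                     (c.ICaL + c.IbCa + c.IpCa - 2.0 * c.INaCa) * Cm /
                     (2.0 * Vc * Frdy));
  double bufsr = 1.0 / (1.0 + Bufsr * Kbufsr / pow(s[iCasr] + Kbufsr, 2.0));
  ds[iCasr] = bufsr * (Vc / Vsr) * (Iup - Irel - Ileak);

  ds[iNai] = -(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) * Cm / (Vc * Frdy);
  ds[iKi]  = -(c.IK1 + c.Ito + c.IKr + c.IKs - 2.0 * c.INaK + c.IpK + istim) *
             Cm / (Vc * Frdy);

  double ginf_[NGATE], gtau[NGATE];
  gate_inf_tau(V, ginf_, gtau);
  for (int g = 0; g < NGATE; ++g)
    ds[GATE_STATE[g]] = (ginf_[g] - s[GATE_STATE[g]]) / gtau[g];

  // fCa and g relax toward their Ca-dependent targets but may not
  // reactivate (increase) while the membrane is depolarized (V > -60 mV)
  double fi; fca_inf(s[iCai], fi);
  ds[ifca] = (fi - s[ifca]) / TAU_FCA;
  if (ds[ifca] > 0.0 && V > -60.0) ds[ifca] = 0.0;
  double gi; g_inf(s[iCai], gi);
  ds[ig] = (gi - s[ig]) / TAU_G;
  if (ds[ig] > 0.0 && V > -60.0) ds[ig] = 0.0;
}

// ---- lookup tables ----
static const double VMIN = -120.0, VMAX = 80.0, VSTEP = 0.01;
static const int NV = (int)((VMAX - VMIN) / VSTEP) + 1;
static const double UMIN = -150.0, UMAX = 250.0;
static const int NU = (int)((UMAX - UMIN) / VSTEP) + 1;

struct Tables {
  double dt = -1.0;
  std::vector<double> inf[NGATE], rlf[NGATE];
  std::vector<double> pkrec, nakrec, nacae1, nacae2, calA, calB;
  std::vector<double> xk1;
};
static Tables TBL;

static void build_tables(double dt) {
  if (TBL.dt == dt) return;
  for (int g = 0; g < NGATE; ++g) { TBL.inf[g].resize(NV); TBL.rlf[g].resize(NV); }
  TBL.pkrec.resize(NV); TBL.nakrec.resize(NV);
  TBL.nacae1.resize(NV); TBL.nacae2.resize(NV);
  TBL.calA.resize(NV); TBL.calB.resize(NV);
  TBL.xk1.resize(NU);
  double ginf_[NGATE], gtau[NGATE];
  for (int k = 0; k < NV; ++k) {
    double V = VMIN + k * VSTEP;
    gate_inf_tau(V, ginf_, gtau);
    for (int g = 0; g < NGATE; ++g) {
      TBL.inf[g][k] = ginf_[g];
      TBL.rlf[g][k] = exp(-dt / gtau[g]);
    }
    TBL.pkrec[k]  = 1.0 / (1.0 + exp((25.0 - V) / 5.98));
    TBL.nakrec[k] = 1.0 / (1.0 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF));
    TBL.nacae1[k] = exp(gam * V / RTF);
    TBL.nacae2[k] = exp((gam - 1.0) * V / RTF);
    double z = 2.0 * V / RTF;
    double q = zexpm1(z);
    TBL.calA[k] = 2.0 * Frdy * q;
    TBL.calB[k] = 2.0 * Frdy * q * exp(z);
  }
  for (int k = 0; k < NU; ++k) {
    double u = UMIN + k * VSTEP;
    double ak1 = 0.1 / (1.0 + exp(0.06 * (u - 200.0)));
    double bk1 = (3.0 * exp(0.0002 * (u + 100.0)) + exp(0.1 * (u - 10.0))) /
                 (1.0 + exp(-0.5 * u));
    TBL.xk1[k] = ak1 / (ak1 + bk1);
  }
  TBL.dt = dt;
}

struct Interp {
  int k; double w;
  Interp(double x, double xmin, int n) {
    double p = (x - xmin) / VSTEP;
    if (p < 0) p = 0;
    if (p > n - 2) p = n - 2;
    k = (int)p; w = p - k;
  }
  inline double operator()(const std::vector<double> &t) const {
    return t[k] + w * (t[k + 1] - t[k]);
  }
};

static inline void currents_tab(const double *s, double sKs, double sKr, double sK1,
                                double ENa, double EK, double EKs, double ECa,
                                const Interp &ip, Currents &c) {
  double V = s[iV];
  c.INa  = Gna * s[im] * s[im] * s[im] * s[ih] * s[ij] * (V - ENa);
  c.ICaL = GcaL * s[id_] * s[if_] * s[ifca] *
           (s[iCai] * ip(TBL.calB) - 0.341 * Cao * ip(TBL.calA));
  c.Ito  = Gto * s[ir] * s[is_] * (V - EK);
  c.IKr  = sKr * Gkr * sqrt(Ko / 5.4) * s[ixr1] * s[ixr2] * (V - EK);
  c.IKs  = sKs * Gks * s[ixs] * s[ixs] * (V - EKs);
  Interp ipu(V - EK, UMIN, NU);
  c.IK1  = sK1 * Gk1 * sqrt(Ko / 5.4) * ipu(TBL.xk1) * (V - EK);
  double e2 = ip(TBL.nacae2);
  c.INaCa = knaca *
      (ip(TBL.nacae1) * pow(s[iNai], 3.0) * Cao - e2 * pow(Nao, 3.0) * s[iCai] * nalph) /
      ((pow(KmNai, 3.0) + pow(Nao, 3.0)) * (KmCa + Cao) * (1.0 + ksat * e2));
  c.INaK = Pnak * Ko * s[iNai] / ((Ko + KmK) * (s[iNai] + KmNa)) * ip(TBL.nakrec);
  c.IpCa = GpCa * s[iCai] / (s[iCai] + KpCa);
  c.IpK  = GpK * (V - EK) * ip(TBL.pkrec);
  c.IbNa = GbNa * (V - ENa);
  c.IbCa = GbCa * (V - ECa);
  c.Iion = c.INa + c.ICaL + c.Ito + c.IKr + c.IKs + c.IK1 + c.INaCa + c.INaK +
           c.IpCa + c.IpK + c.IbNa + c.IbCa;
}

static inline void step_tab(double *s, double sKs, double sKr, double sK1,
                            double istim, double dt, Currents &c) {
  Interp ip(s[iV], VMIN, NV);
  double V = s[iV];
  double ENa = RTF * log(Nao / s[iNai]);
  double EK  = RTF * log(Ko / s[iKi]);
  double EKs = RTF * log((Ko + pKNa * Nao) / (s[iKi] + pKNa * s[iNai]));
  double ECa = 0.5 * RTF * log(Cao / s[iCai]);
  currents_tab(s, sKs, sKr, sK1, ENa, EK, EKs, ECa, ip, c);

  double Ileak = Vleak * (s[iCasr] - s[iCai]);
  double Iup   = Vmaxup / (1.0 + pow(Kup / s[iCai], 2.0));
  double Irel  = (arel * s[iCasr] * s[iCasr] / (brel * brel + s[iCasr] * s[iCasr]) +
                  crel) * s[id_] * s[ig];
  double bufc  = 1.0 / (1.0 + Bufc * Kbufc / pow(s[iCai] + Kbufc, 2.0));
  double dCai  = bufc * (Ileak - Iup + Irel -
                         (c.ICaL + c.IbCa + c.IpCa - 2.0 * c.INaCa) * Cm /
                         (2.0 * Vc * Frdy));
  double bufsr = 1.0 / (1.0 + Bufsr * Kbufsr / pow(s[iCasr] + Kbufsr, 2.0));
  double dCasr = bufsr * (Vc / Vsr) * (Iup - Irel - Ileak);
  double dNai = -(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) * Cm / (Vc * Frdy);
  double dKi  = -(c.IK1 + c.Ito + c.IKr + c.IKs - 2.0 * c.INaK + c.IpK + istim) *
                Cm / (Vc * Frdy);

  for (int g = 0; g < NGATE; ++g) {
    int ix = GATE_STATE[g];
    double inf = ip(TBL.inf[g]);
    double rlf = ip(TBL.rlf[g]);
    s[ix] = inf + (s[ix] - inf) * rlf;
  }
  // fCa/g: exponential relaxation, frozen when it would increase at V > -60
  double fi; fca_inf(s[iCai], fi);
  double fnew = fi + (s[ifca] - fi) * exp(-dt / TAU_FCA);
  if (!(fnew > s[ifca] && V > -60.0)) s[ifca] = fnew;
  double gi; g_inf(s[iCai], gi);
  double gnew = gi + (s[ig] - gi) * exp(-dt / TAU_G);
  if (!(gnew > s[ig] && V > -60.0)) s[ig] = gnew;

  s[iV]    += dt * (-(c.Iion + istim));
  s[iNai]  += dt * dNai;
  s[iKi]   += dt * dKi;
  s[iCai]  += dt * dCai;
  s[iCasr] += dt * dCasr;
}

static void check_state(const NumericVector &state) {
  if (state.size() != NSTATE)
    stop("state must have %d components", NSTATE);
  for (int i = 0; i < NSTATE; ++i)
    if (!R_finite(state[i]))
      stop("invalid state: component '%s' is not finite", STATE_NAMES[i]);
}

} // namespace tnnp04

using namespace tnnp04;

// [[Rcpp::export]]
NumericVector cpp_tnnp04_init() {
  NumericVector out(tnnp04::NSTATE);
  CharacterVector nm(tnnp04::NSTATE);
  for (int i = 0; i < tnnp04::NSTATE; ++i) {
    out[i] = tnnp04::INIT_STATE[i]; nm[i] = tnnp04::STATE_NAMES[i];
  }
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tnnp04_derivs(NumericVector state, double sKs, double sKr,
                                double sK1, double istim) {
  tnnp04::check_state(state);
  if (!R_finite(istim)) stop("istim must be finite");
  NumericVector out(tnnp04::NSTATE);
  tnnp04::compute_derivs(REAL(state), sKs, sKr, sK1, istim, REAL(out));
  out.attr("names") = state.attr("names");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tnnp04_currents(NumericVector state, double sKs, double sKr,
                                  double sK1) {
  tnnp04::check_state(state);
  tnnp04::Currents c;
  tnnp04::compute_currents(REAL(state), sKs, sKr, sK1, c);
  return NumericVector::create(
      _["INa"] = c.INa, _["ICaL"] = c.ICaL, _["Ito"] = c.Ito, _["IKr"] = c.IKr,
      _["IKs"] = c.IKs, _["IK1"] = c.IK1, _["INaCa"] = c.INaCa,
      _["INaK"] = c.INaK, _["IpCa"] = c.IpCa, _["IpK"] = c.IpK,
      _["IbNa"] = c.IbNa, _["IbCa"] = c.IbCa, _["Iion"] = c.Iion);
}

// [[Rcpp::export]]
NumericVector cpp_tnnp04_step(NumericVector state, double sKs, double sKr,
                              double sK1, double istim, double dt) {
  tnnp04::check_state(state);
  if (dt <= 0 || dt > 0.05) stop("dt must be in (0, 0.05] ms");
  NumericVector out = clone(state);
  double *s = REAL(out);
  double V = s[tnnp04::iV];
  double ds[tnnp04::NSTATE];
  tnnp04::compute_derivs(s, sKs, sKr, sK1, istim, ds);
  double ginf_[tnnp04::NGATE], gtau[tnnp04::NGATE];
  tnnp04::gate_inf_tau(V, ginf_, gtau);
  for (int g = 0; g < tnnp04::NGATE; ++g) {
    int ix = tnnp04::GATE_STATE[g];
    s[ix] = ginf_[g] + (s[ix] - ginf_[g]) * exp(-dt / gtau[g]);
  }
  double fi; tnnp04::fca_inf(s[tnnp04::iCai], fi);
  double fnew = fi + (s[tnnp04::ifca] - fi) * exp(-dt / tnnp04::TAU_FCA);
  if (!(fnew > s[tnnp04::ifca] && V > -60.0)) s[tnnp04::ifca] = fnew;
  double gi; tnnp04::g_inf(s[tnnp04::iCai], gi);
  double gnew = gi + (s[tnnp04::ig] - gi) * exp(-dt / tnnp04::TAU_G);
  if (!(gnew > s[tnnp04::ig] && V > -60.0)) s[tnnp04::ig] = gnew;
  s[tnnp04::iV]    += dt * ds[tnnp04::iV];
  s[tnnp04::iNai]  += dt * ds[tnnp04::iNai];
  s[tnnp04::iKi]   += dt * ds[tnnp04::iKi];
  s[tnnp04::iCai]  += dt * ds[tnnp04::iCai];
  s[tnnp04::iCasr] += dt * ds[tnnp04::iCasr];
  for (int i = 0; i < tnnp04::NSTATE; ++i)
    if (!R_finite(s[i]))
      stop("integration blow-up at step: variable '%s' non-finite",
           tnnp04::STATE_NAMES[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tnnp04_step_tab(NumericVector state, double sKs, double sKr,
                                  double sK1, double istim, double dt) {
  tnnp04::check_state(state);
  if (dt <= 0 || dt > 0.05) stop("dt must be in (0, 0.05] ms");
  tnnp04::build_tables(dt);
  NumericVector out = clone(state);
  tnnp04::Currents c;
  tnnp04::step_tab(REAL(out), sKs, sKr, sK1, istim, dt, c);
  return out;
}

// [[Rcpp::export]]
List cpp_tnnp04_pace(NumericVector init_state, double sKs, double sKr, double sK1,
                     double stim_amp, double stim_dur, double bcl, int n_beats,
                     double dt, double sample_ms, double inject_amp,
                     bool record_last, bool record_all) {
  tnnp04::check_state(init_state);
  if (dt <= 0 || dt > 0.05) stop("dt must be in (0, 0.05] ms");
  if (bcl <= stim_dur) stop("bcl must exceed the stimulus duration");
  if (n_beats < 1) stop("n_beats must be >= 1");
  tnnp04::build_tables(dt);

  double s[tnnp04::NSTATE];
  for (int i = 0; i < tnnp04::NSTATE; ++i) s[i] = init_state[i];

  int steps_per_beat = (int)llround(bcl / dt);
  int sample_every = (int)llround(sample_ms / dt);
  if (sample_every < 1) sample_every = 1;
  int stim_steps = (int)llround(stim_dur / dt);

  NumericVector b_takeoff(n_beats), b_peak(n_beats), b_tpeak(n_beats),
      b_tup(n_beats), b_apd90(n_beats), b_vmax10(n_beats);
  LogicalVector b_capture(n_beats);

  std::vector<double> tr_t, tr_v, tr_iks, tr_ikr, tr_ik1, tr_iion;
  int est = record_all ? n_beats * (steps_per_beat / sample_every + 2)
                       : (steps_per_beat / sample_every + 2);
  if (record_last || record_all) {
    tr_t.reserve(est); tr_v.reserve(est); tr_iks.reserve(est);
    tr_ikr.reserve(est); tr_ik1.reserve(est); tr_iion.reserve(est);
  }

  NumericVector last_beat_state(tnnp04::NSTATE);
  bool repol_fail = false;
  tnnp04::Currents c;

  for (int beat = 0; beat < n_beats; ++beat) {
    bool last = (beat == n_beats - 1);
    bool rec = record_all || (record_last && last);
    if (last) for (int i = 0; i < tnnp04::NSTATE; ++i) last_beat_state[i] = s[i];

    double takeoff = s[tnnp04::iV];
    double peak = s[tnnp04::iV], tpeak = 0.0;
    double vmax10 = s[tnnp04::iV];
    double maxdv = -1e30, tup = 0.0;
    double apd90 = NA_REAL;
    bool crossed = false;
    bool injecting = last && inject_amp != 0.0;

    for (int k = 0; k < steps_per_beat; ++k) {
      double tloc = k * dt;
      double istim = (k < stim_steps) ? -stim_amp : 0.0;
      if (injecting && !crossed) istim += inject_amp;

      if (rec && (k % sample_every == 0)) {
        tnnp04::Interp ip(s[tnnp04::iV], tnnp04::VMIN, tnnp04::NV);
        double ENa = tnnp04::RTF * log(tnnp04::Nao / s[tnnp04::iNai]);
        double EK  = tnnp04::RTF * log(tnnp04::Ko / s[tnnp04::iKi]);
        double EKs = tnnp04::RTF * log((tnnp04::Ko + tnnp04::pKNa * tnnp04::Nao) /
                                       (s[tnnp04::iKi] + tnnp04::pKNa * s[tnnp04::iNai]));
        double ECa = 0.5 * tnnp04::RTF * log(tnnp04::Cao / s[tnnp04::iCai]);
        tnnp04::Currents cr;
        tnnp04::currents_tab(s, sKs, sKr, sK1, ENa, EK, EKs, ECa, ip, cr);
        tr_t.push_back(record_all ? beat * bcl + tloc : tloc);
        tr_v.push_back(s[tnnp04::iV]);
        tr_iks.push_back(cr.IKs); tr_ikr.push_back(cr.IKr);
        tr_ik1.push_back(cr.IK1); tr_iion.push_back(cr.Iion);
      }

      double vold = s[tnnp04::iV];
      tnnp04::step_tab(s, sKs, sKr, sK1, istim, dt, c);
      double vnew = s[tnnp04::iV];

      if (vnew != vnew || fabs(vnew) > 1000.0)
        stop("integration blow-up at t = %.3f ms (beat %d): Vm non-finite or out of range",
             beat * bcl + tloc, beat + 1);

      double dv = (vnew - vold) / dt;
      if (dv > maxdv) { maxdv = dv; tup = tloc + dt; }
      if (vnew > peak) { peak = vnew; tpeak = tloc + dt; }
      if (tloc + dt <= 10.0 && vnew > vmax10) vmax10 = vnew;

      if (!crossed && tloc + dt > tpeak && peak > -40.0) {
        double thr = peak - 0.9 * (peak - takeoff);
        if (vold > thr && vnew <= thr) {
          double tc = tloc + dt * (vold - thr) / (vold - vnew);
          apd90 = tc - tup;
          crossed = true;
        }
      }
    }

    b_takeoff[beat] = takeoff; b_peak[beat] = peak; b_tpeak[beat] = tpeak;
    b_tup[beat] = tup; b_apd90[beat] = apd90; b_vmax10[beat] = vmax10;
    b_capture[beat] = vmax10 > 0.0;
    if (last && !crossed && b_capture[beat]) repol_fail = true;

    for (int i = 0; i < tnnp04::NSTATE; ++i)
      if (!R_finite(s[i]))
        stop("integration blow-up after beat %d: variable '%s' non-finite",
             beat + 1, tnnp04::STATE_NAMES[i]);
  }

  NumericVector final_state(tnnp04::NSTATE);
  CharacterVector nm(tnnp04::NSTATE);
  for (int i = 0; i < tnnp04::NSTATE; ++i) {
    final_state[i] = s[i]; nm[i] = tnnp04::STATE_NAMES[i];
  }
  final_state.attr("names") = nm;
  last_beat_state.attr("names") = nm;

  RObject trace = R_NilValue;
  if (record_last || record_all) {
    int n = (int)tr_t.size();
    NumericMatrix m(n, 6);
    for (int r = 0; r < n; ++r) {
      m(r, 0) = tr_t[r]; m(r, 1) = tr_v[r]; m(r, 2) = tr_iks[r];
      m(r, 3) = tr_ikr[r]; m(r, 4) = tr_ik1[r]; m(r, 5) = tr_iion[r];
    }
    colnames(m) = CharacterVector::create("time_ms", "Vm_mV", "IKs", "IKr",
                                          "IK1", "Iion");
    trace = m;
  }

  return List::create(
      _["takeoff"] = b_takeoff, _["peak"] = b_peak, _["t_peak"] = b_tpeak,
      _["t_upstroke"] = b_tup, _["apd90"] = b_apd90, _["vmax10"] = b_vmax10,
      _["captured"] = b_capture, _["trace"] = trace,
      _["final_state"] = final_state, _["last_beat_state"] = last_beat_state,
      _["repol_fail"] = repol_fail);
}
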