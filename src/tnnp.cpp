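// ten Tusscher - Panfilov (2006) human ventricular epicardial cell model,
// CellML-distributed parameterization, with scalable maximal conductances for
// IKs, IKr and IK1. Exact (closed-form) rate evaluation is exposed for
// derivative/current queries; the pacing driver uses voltage lookup tables
// (0.01 mV grid) for the Rush-Larsen gate updates and voltage-dependent
// current factors, rebuilt whenever dt changes.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- physical constants and model parameters (epicardial variant) ----
static const double Rgas = 8314.472;     // mJ/(mol K)
static const double Temp = 310.0;        // K
static const double Frdy = 96485.3415;   // C/mol
static const double RTF  = Rgas * Temp / Frdy;

static const double Ko  = 5.4;   // mM
static const double Nao = 140.0; // mM
static const double Cao = 2.0;   // mM

static const double Gna   = 14.838;
static const double GcaL  = 3.98e-5;
static const double Gto   = 0.294;   // epi
static const double Gkr   = 0.153;
static const double Gks   = 0.392;   // epi
static const double Gk1   = 5.405;
static const double GpCa  = 0.1238;
static const double GpK   = 0.0146;
static const double GbNa  = 0.00029;
static const double GbCa  = 0.000592;

static const double pKNa  = 0.03;
static const double Pnak  = 2.724;
static const double KmK   = 1.0;
static const double KmNa  = 40.0;
static const double knaca = 1000.0;
static const double KmNai = 87.5;
static const double KmCa  = 1.38;
static const double ksat  = 0.1;
static const double nalph = 2.5;
static const double gam   = 0.35;
static const double KpCa  = 0.0005;

static const double Cm   = 0.185;     // uF
static const double Vc   = 0.016404;
static const double Vsr  = 0.001094;
static const double Vss  = 0.00005468;

static const double Bufc   = 0.2,  Kbufc  = 0.001;
static const double Bufsr  = 10.0, Kbufsr = 0.3;
static const double Bufss  = 0.4,  Kbufss = 0.00025;
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel   = 0.102, Vleak = 0.00036, Vxfer = 0.0038;
static const double k1p = 0.15, k2p = 0.045, k3r = 0.060, k4r = 0.005;
static const double ECsr = 1.5, maxsr = 2.5, minsr = 1.0;

// state vector layout
enum { iV = 0, iNai, iKi, iCai, iCass, iCasr, iRpr,
       im, ih, ij, id_, if_, if2, ifca, ir, is_, ixr1, ixr2, ixs, NSTATE };

static const char *STATE_NAMES[NSTATE] = {
  "Vm", "Nai", "Ki", "Cai", "Cass", "Casr", "Rprime",
  "m", "h", "j", "d", "f", "f2", "fCass", "r", "s", "xr1", "xr2", "xs" };

// published initial conditions (CellML 2006 epicardial)
static const double INIT_STATE[NSTATE] = {
  -85.23,      // Vm
  8.604,       // Nai
  136.89,      // Ki
  0.000126,    // Cai
  0.00036,     // Cass
  3.64,        // Casr
  0.9073,      // Rprime
  0.00172,     // m
  0.7444,      // h
  0.7045,      // j
  3.373e-5,    // d
  0.7888,      // f
  0.9755,      // f2
  0.9953,      // fCass
  2.42e-8,     // r
  0.999998,    // s
  0.00621,     // xr1
  0.4712,      // xr2
  0.0095       // xs
};

// voltage-dependent gates handled by Rush-Larsen tables
enum { GM = 0, GH, GJ, GD, GF, GF2, GR, GS, GXR1, GXR2, GXS, NGATE };
static const int GATE_STATE[NGATE] = { im, ih, ij, id_, if_, if2, ir, is_, ixr1, ixr2, ixs };

static void gate_inf_tau(double V, double *inf, double *tau) {
  // INa gates
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
  // ICaL voltage gates
  inf[GD] = 1.0 / (1.0 + exp((-8.0 - V) / 7.5));
  {
    double ad = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
    double bd = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
    double gd = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
    tau[GD] = ad * bd + gd;
  }
  inf[GF] = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
  tau[GF] = 1102.5 * exp(-pow(V + 27.0, 2.0) / 225.0) +
            200.0 / (1.0 + exp((13.0 - V) / 10.0)) +
            180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;
  inf[GF2] = 0.67 / (1.0 + exp((V + 35.0) / 7.0)) + 0.33;
  tau[GF2] = 562.0 * exp(-pow(V + 27.0, 2.0) / 240.0) +
             31.0 / (1.0 + exp((25.0 - V) / 10.0)) +
             80.0 / (1.0 + exp((V + 30.0) / 10.0));
  // Ito gates (epi s)
  inf[GR] = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
  tau[GR] = 9.5 * exp(-pow(V + 40.0, 2.0) / 1800.0) + 0.8;
  inf[GS] = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
  tau[GS] = 85.0 * exp(-pow(V + 45.0, 2.0) / 320.0) +
            5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;
  // IKr gates
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
  // IKs gate
  inf[GXS] = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
  {
    double a = 1400.0 / sqrt(1.0 + exp((5.0 - V) / 6.0));
    double b = 1.0 / (1.0 + exp((V - 35.0) / 15.0));
    tau[GXS] = a * b + 80.0;
  }
}

static void fcass_inf_tau(double Cass, double &inf, double &tau) {
  double u = 1.0 / (1.0 + pow(Cass / 0.05, 2.0));
  inf = 0.6 * u + 0.4;
  tau = 80.0 * u + 2.0;
}

struct Currents {
  double INa, ICaL, Ito, IKr, IKs, IK1, INaCa, INaK, IpCa, IpK, IbNa, IbCa, Iion;
};

// z/(exp(z)-1), stable near z = 0
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

  double z = 2.0 * (V - 15.0) / RTF;
  double q = zexpm1(z);           // z/(e^z - 1)
  // ICaL = GcaL*d*f*f2*fCass * 2F * q * (0.25*Cass*e^z - Cao)
  c.ICaL = GcaL * s[id_] * s[if_] * s[if2] * s[ifca] * 2.0 * Frdy * q *
           (0.25 * s[iCass] * exp(z) - Cao);

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

// full exact right-hand side; istim in pA/pF, inward (depolarizing) negative
static void compute_derivs(const double *s, double sKs, double sKr, double sK1,
                           double istim, double *ds) {
  Currents c;
  compute_currents(s, sKs, sKr, sK1, c);

  ds[iV] = -(c.Iion + istim);

  // calcium subsystem
  double kcasr = maxsr - (maxsr - minsr) / (1.0 + pow(ECsr / s[iCasr], 2.0));
  double k1 = k1p / kcasr;
  double k2 = k2p * kcasr;
  double O = k1 * s[iCass] * s[iCass] * s[iRpr] / (k3r + k1 * s[iCass] * s[iCass]);
  ds[iRpr] = -k2 * s[iCass] * s[iRpr] + k4r * (1.0 - s[iRpr]);
  double Irel  = Vrel * O * (s[iCasr] - s[iCass]);
  double Ileak = Vleak * (s[iCasr] - s[iCai]);
  double Iup   = Vmaxup / (1.0 + pow(Kup / s[iCai], 2.0));
  double Ixfer = Vxfer * (s[iCass] - s[iCai]);

  double bufc = 1.0 / (1.0 + Bufc * Kbufc / pow(s[iCai] + Kbufc, 2.0));
  ds[iCai] = bufc * ((Ileak - Iup) * Vsr / Vc + Ixfer -
                     (c.IbCa + c.IpCa - 2.0 * c.INaCa) * Cm / (2.0 * Vc * Frdy));
  double bufsr = 1.0 / (1.0 + Bufsr * Kbufsr / pow(s[iCasr] + Kbufsr, 2.0));
  ds[iCasr] = bufsr * (Iup - Irel - Ileak);
  double bufss = 1.0 / (1.0 + Bufss * Kbufss / pow(s[iCass] + Kbufss, 2.0));
  ds[iCass] = bufss * (-c.ICaL * Cm / (2.0 * Vss * Frdy) + Irel * Vsr / Vss -
                       Ixfer * Vc / Vss);

  ds[iNai] = -(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) * Cm / (Vc * Frdy);
  ds[iKi]  = -(c.IK1 + c.Ito + c.IKr + c.IKs - 2.0 * c.INaK + c.IpK + istim) *
             Cm / (Vc * Frdy);

  double ginf[NGATE], gtau[NGATE];
  gate_inf_tau(s[iV], ginf, gtau);
  for (int g = 0; g < NGATE; ++g)
    ds[GATE_STATE[g]] = (ginf[g] - s[GATE_STATE[g]]) / gtau[g];
  double fci, fct;
  fcass_inf_tau(s[iCass], fci, fct);
  ds[ifca] = (fci - s[ifca]) / fct;
}

// ---- lookup tables for the pacing fast path ----
static const double VMIN = -120.0, VMAX = 80.0, VSTEP = 0.01;
static const int NV = (int)((VMAX - VMIN) / VSTEP) + 1;
static const double UMIN = -150.0, UMAX = 250.0;  // u = V - EK for IK1
static const int NU = (int)((UMAX - UMIN) / VSTEP) + 1;

struct Tables {
  double dt = -1.0;
  std::vector<double> inf[NGATE], rlf[NGATE];   // gate x_inf, exp(-dt/tau)
  std::vector<double> pkrec, nakrec, nacae1, nacae2, calA, calB;
  std::vector<double> xk1;                      // on u = V - EK grid
};
static Tables TBL;

static void build_tables(double dt) {
  if (TBL.dt == dt) return;
  for (int g = 0; g < NGATE; ++g) { TBL.inf[g].resize(NV); TBL.rlf[g].resize(NV); }
  TBL.pkrec.resize(NV); TBL.nakrec.resize(NV);
  TBL.nacae1.resize(NV); TBL.nacae2.resize(NV);
  TBL.calA.resize(NV); TBL.calB.resize(NV);
  TBL.xk1.resize(NU);
  double ginf[NGATE], gtau[NGATE];
  for (int k = 0; k < NV; ++k) {
    double V = VMIN + k * VSTEP;
    gate_inf_tau(V, ginf, gtau);
    for (int g = 0; g < NGATE; ++g) {
      TBL.inf[g][k] = ginf[g];
      TBL.rlf[g][k] = exp(-dt / gtau[g]);
    }
    TBL.pkrec[k]  = 1.0 / (1.0 + exp((25.0 - V) / 5.98));
    TBL.nakrec[k] = 1.0 / (1.0 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF));
    TBL.nacae1[k] = exp(gam * V / RTF);
    TBL.nacae2[k] = exp((gam - 1.0) * V / RTF);
    double z = 2.0 * (V - 15.0) / RTF;
    double q = zexpm1(z);
    TBL.calA[k] = 2.0 * Frdy * q;            // multiplies -Cao
    TBL.calB[k] = 2.0 * Frdy * q * exp(z);   // multiplies 0.25*Cass
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

// table-based currents; EK passed in (u-grid lookup for IK1)
static inline void currents_tab(const double *s, double sKs, double sKr, double sK1,
                                double ENa, double EK, double EKs, double ECa,
                                const Interp &ip, Currents &c) {
  double V = s[iV];
  c.INa  = Gna * s[im] * s[im] * s[im] * s[ih] * s[ij] * (V - ENa);
  c.ICaL = GcaL * s[id_] * s[if_] * s[if2] * s[ifca] *
           (0.25 * s[iCass] * ip(TBL.calB) - Cao * ip(TBL.calA));
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

// one table-based integration step (Rush-Larsen gates, Euler otherwise);
// returns Iion of the pre-step state through `c`.
static inline void step_tab(double *s, double sKs, double sKr, double sK1,
                            double istim, double dt, Currents &c) {
  Interp ip(s[iV], VMIN, NV);
  double ENa = RTF * log(Nao / s[iNai]);
  double EK  = RTF * log(Ko / s[iKi]);
  double EKs = RTF * log((Ko + pKNa * Nao) / (s[iKi] + pKNa * s[iNai]));
  double ECa = 0.5 * RTF * log(Cao / s[iCai]);
  currents_tab(s, sKs, sKr, sK1, ENa, EK, EKs, ECa, ip, c);

  double kcasr = maxsr - (maxsr - minsr) / (1.0 + pow(ECsr / s[iCasr], 2.0));
  double k1 = k1p / kcasr;
  double k2 = k2p * kcasr;
  double O = k1 * s[iCass] * s[iCass] * s[iRpr] / (k3r + k1 * s[iCass] * s[iCass]);
  double dRpr = -k2 * s[iCass] * s[iRpr] + k4r * (1.0 - s[iRpr]);
  double Irel  = Vrel * O * (s[iCasr] - s[iCass]);
  double Ileak = Vleak * (s[iCasr] - s[iCai]);
  double Iup   = Vmaxup / (1.0 + pow(Kup / s[iCai], 2.0));
  double Ixfer = Vxfer * (s[iCass] - s[iCai]);
  double bufc  = 1.0 / (1.0 + Bufc * Kbufc / pow(s[iCai] + Kbufc, 2.0));
  double dCai  = bufc * ((Ileak - Iup) * Vsr / Vc + Ixfer -
                         (c.IbCa + c.IpCa - 2.0 * c.INaCa) * Cm / (2.0 * Vc * Frdy));
  double bufsr = 1.0 / (1.0 + Bufsr * Kbufsr / pow(s[iCasr] + Kbufsr, 2.0));
  double dCasr = bufsr * (Iup - Irel - Ileak);
  double bufss = 1.0 / (1.0 + Bufss * Kbufss / pow(s[iCass] + Kbufss, 2.0));
  double dCass = bufss * (-c.ICaL * Cm / (2.0 * Vss * Frdy) + Irel * Vsr / Vss -
                          Ixfer * Vc / Vss);
  double dNai = -(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) * Cm / (Vc * Frdy);
  double dKi  = -(c.IK1 + c.Ito + c.IKr + c.IKs - 2.0 * c.INaK + c.IpK + istim) *
                Cm / (Vc * Frdy);

  // Rush-Larsen exponential gate updates from tables
  for (int g = 0; g < NGATE; ++g) {
    int ix = GATE_STATE[g];
    double inf = ip(TBL.inf[g]);
    double rlf = ip(TBL.rlf[g]);
    s[ix] = inf + (s[ix] - inf) * rlf;
  }
  double fci, fct;
  fcass_inf_tau(s[iCass], fci, fct);
  s[ifca] = fci + (s[ifca] - fci) * exp(-dt / fct);

  s[iV]    += dt * (-(c.Iion + istim));
  s[iNai]  += dt * dNai;
  s[iKi]   += dt * dKi;
  s[iCai]  += dt * dCai;
  s[iCass] += dt * dCass;
  s[iCasr] += dt * dCasr;
  s[iRpr]  += dt * dRpr;
}

static void check_state(const NumericVector &state) {
  if (state.size() != NSTATE)
    stop("state must have %d components", NSTATE);
  for (int i = 0; i < NSTATE; ++i)
    if (!R_finite(state[i]))
      stop("invalid state: component '%s' is not finite", STATE_NAMES[i]);
}

// [[Rcpp::export]]
NumericVector cpp_tnnp_init() {
  NumericVector out(NSTATE);
  CharacterVector nm(NSTATE);
  for (int i = 0; i < NSTATE; ++i) { out[i] = INIT_STATE[i]; nm[i] = STATE_NAMES[i]; }
  out.attr("names") = nm;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tnnp_derivs(NumericVector state, double sKs, double sKr,
                              double sK1, double istim) {
  check_state(state);
  if (!R_finite(istim)) stop("istim must be finite");
  NumericVector out(NSTATE);
  compute_derivs(REAL(state), sKs, sKr, sK1, istim, REAL(out));
  out.attr("names") = state.attr("names");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tnnp_currents(NumericVector state, double sKs, double sKr,
                                double sK1) {
  check_state(state);
  Currents c;
  compute_currents(REAL(state), sKs, sKr, sK1, c);
  return NumericVector::create(
      _["INa"] = c.INa, _["ICaL"] = c.ICaL, _["Ito"] = c.Ito, _["IKr"] = c.IKr,
      _["IKs"] = c.IKs, _["IK1"] = c.IK1, _["INaCa"] = c.INaCa,
      _["INaK"] = c.INaK, _["IpCa"] = c.IpCa, _["IpK"] = c.IpK,
      _["IbNa"] = c.IbNa, _["IbCa"] = c.IbCa, _["Iion"] = c.Iion);
}

// single exact Rush-Larsen/Euler step (no tables); used for verification
// [[Rcpp::export]]
NumericVector cpp_tnnp_step(NumericVector state, double sKs, double sKr,
                            double sK1, double istim, double dt) {
  check_state(state);
  if (dt <= 0 || dt > 0.05) stop("dt must be in (0, 0.05] ms");
  NumericVector out = clone(state);
  double *s = REAL(out);
  double ds[NSTATE];
  compute_derivs(s, sKs, sKr, sK1, istim, ds);
  double ginf[NGATE], gtau[NGATE];
  gate_inf_tau(s[iV], ginf, gtau);
  for (int g = 0; g < NGATE; ++g) {
    int ix = GATE_STATE[g];
    s[ix] = ginf[g] + (s[ix] - ginf[g]) * exp(-dt / gtau[g]);
  }
  double fci, fct;
  fcass_inf_tau(s[iCass], fci, fct);
  s[ifca] = fci + (s[ifca] - fci) * exp(-dt / fct);
  s[iV]    += dt * ds[iV];
  s[iNai]  += dt * ds[iNai];
  s[iKi]   += dt * ds[iKi];
  s[iCai]  += dt * ds[iCai];
  s[iCass] += dt * ds[iCass];
  s[iCasr] += dt * ds[iCasr];
  s[iRpr]  += dt * ds[iRpr];
  for (int i = 0; i < NSTATE; ++i)
    if (!R_finite(s[i]))
      stop("integration blow-up at step: variable '%s' non-finite", STATE_NAMES[i]);
  return out;
}

// one table-based step, exposed so tests can compare against cpp_tnnp_step
// [[Rcpp::export]]
NumericVector cpp_tnnp_step_tab(NumericVector state, double sKs, double sKr,
                                double sK1, double istim, double dt) {
  check_state(state);
  if (dt <= 0 || dt > 0.05) stop("dt must be in (0, 0.05] ms");
  build_tables(dt);
  NumericVector out = clone(state);
  Currents c;
  step_tab(REAL(out), sKs, sKr, sK1, istim, dt, c);
  return out;
}

// Pacing driver. Stimulus: rectangular pulse of magnitude stim_amp (pA/pF,
// applied inward, i.e. istim = -stim_amp) for stim_dur ms at the start of each
// cycle. inject_amp (signed, pA/pF) is an extra constant current applied during
// the final beat from stimulus onset until its APD90 crossing. Records the
// final beat (or the whole run) sampled every sample_ms.
// [[Rcpp::export]]
List cpp_tnnp_pace(NumericVector init_state, double sKs, double sKr, double sK1,
                   double stim_amp, double stim_dur, double bcl, int n_beats,
                   double dt, double sample_ms, double inject_amp,
                   bool record_last, bool record_all) {
  check_state(init_state);
  if (dt <= 0 || dt > 0.05) stop("dt must be in (0, 0.05] ms");
  if (bcl <= stim_dur) stop("bcl must exceed the stimulus duration");
  if (n_beats < 1) stop("n_beats must be >= 1");
  build_tables(dt);

  double s[NSTATE];
  for (int i = 0; i < NSTATE; ++i) s[i] = init_state[i];

  int steps_per_beat = (int)llround(bcl / dt);
  int sample_every = (int)llround(sample_ms / dt);
  if (sample_every < 1) sample_every = 1;
  int stim_steps = (int)llround(stim_dur / dt);

  NumericVector b_takeoff(n_beats), b_peak(n_beats), b_tpeak(n_beats),
      b_tup(n_beats), b_apd90(n_beats), b_vmax10(n_beats);
  LogicalVector b_capture(n_beats);

  // trace buffers
  std::vector<double> tr_t, tr_v, tr_iks, tr_ikr, tr_ik1, tr_iion;
  int est = record_all ? n_beats * (steps_per_beat / sample_every + 2)
                       : (steps_per_beat / sample_every + 2);
  if (record_last || record_all) {
    tr_t.reserve(est); tr_v.reserve(est); tr_iks.reserve(est);
    tr_ikr.reserve(est); tr_ik1.reserve(est); tr_iion.reserve(est);
  }

  NumericVector last_beat_state(NSTATE);
  bool repol_fail = false;
  Currents c;

  for (int beat = 0; beat < n_beats; ++beat) {
    bool last = (beat == n_beats - 1);
    bool rec = record_all || (record_last && last);
    if (last) for (int i = 0; i < NSTATE; ++i) last_beat_state[i] = s[i];

    double takeoff = s[iV];
    double peak = s[iV], tpeak = 0.0;
    double vmax10 = s[iV];
    double maxdv = -1e30, tup = 0.0;
    double apd90 = NA_REAL;
    bool crossed = false;
    bool injecting = last && inject_amp != 0.0;

    for (int k = 0; k < steps_per_beat; ++k) {
      double tloc = k * dt;
      double istim = (k < stim_steps) ? -stim_amp : 0.0;
      if (injecting && !crossed) istim += inject_amp;

      if (rec && (k % sample_every == 0)) {
        // record pre-step sample (k = 0 row is the pre-stimulus state)
        Interp ip(s[iV], VMIN, NV);
        double ENa = RTF * log(Nao / s[iNai]);
        double EK  = RTF * log(Ko / s[iKi]);
        double EKs = RTF * log((Ko + pKNa * Nao) / (s[iKi] + pKNa * s[iNai]));
        double ECa = 0.5 * RTF * log(Cao / s[iCai]);
        Currents cr;
        currents_tab(s, sKs, sKr, sK1, ENa, EK, EKs, ECa, ip, cr);
        tr_t.push_back(record_all ? beat * bcl + tloc : tloc);
        tr_v.push_back(s[iV]);
        tr_iks.push_back(cr.IKs); tr_ikr.push_back(cr.IKr);
        tr_ik1.push_back(cr.IK1); tr_iion.push_back(cr.Iion);
      }

      double vold = s[iV];
      step_tab(s, sKs, sKr, sK1, istim, dt, c);
      double vnew = s[iV];

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

    for (int i = 0; i < NSTATE; ++i)
      if (!R_finite(s[i]))
        stop("integration blow-up after beat %d: variable '%s' non-finite",
             beat + 1, STATE_NAMES[i]);
  }

  NumericVector final_state(NSTATE);
  CharacterVector nm(NSTATE);
  for (int i = 0; i < NSTATE; ++i) { final_state[i] = s[i]; nm[i] = STATE_NAMES[i]; }
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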