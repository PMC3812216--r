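// Closed-loop 0-D cardiovascular model: four elastance chambers with septal
// and pericardial coupling, inertial valves, six parallel systemic branches
// with hydrostatic columns, pulmonary loop, arterial + cardiopulmonary
// baroreflexes, and lower-body myogenic autoregulation.
//
// The integrator is a fixed-step classical RK4 loop with per-step valve
// zero-crossing clamping (flow states are held at zero while a valve is
// closed and the pressure gradient is adverse). Sympathetic/vagal drives
// reach the effectors through pure transport delays implemented as ring
// buffers, which a fixed step makes exact.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

static const int NST = 38;
// state layout
enum {
  iVlv = 0, iVrv, iVla, iVra, iVsa,
  iVbp, iVbv, iVup, iVuv, iVhp, iVhv, iVsp, iVsv, iVkp, iVkv, iVlbp, iVlbv,
  iVtv, iVpa, iVpc, iVpu,
  iQmt, iQav, iQtc, iQpv,
  iPtl,
  iRup, iRsp, iRkp, iRlb,
  iVuuv, iVusv, iVukv, iVulbv,
  iElv, iErv, iTef, iPcvf
};

struct Ch { double Ees, V0, P0, lam; };

struct Pars {
  Ch lvf, rvf, spt, la, ra;
  double peri_P0, peri_lam, peri_V0, Vmyo;
  int peri_dynamic; double peri_frozen;
  double s_sys_v, atr_off, d_a;
  double Rmt, Lmt, Rav, Lav, Rtc, Ltc, Rpv, Lpv;
  double khyd;                       // mmHg per cm of column at sin(alpha)=1
  double collapse_k;                 // compliance stiffening when collapsed
  double C_sa, Vu_sa;
  double C_tv, Vu_tv, R_tv;
  // branch order: cerebral, upper, coronary, splanchnic, renal, lower
  double Cp[6], Vup[6], Cv[6], Vuv[6], Ra[6], Rm[6], Rv[6], hh[6];
  double Vmax_lb;
  double sP_dist, s_kdist;           // splanchnic venous distension stiffening
  double C_pa, Vu_pa, R_pa, C_pc, Vu_pc, R_pc, C_pu, Vu_pu, R_pu;
  double Pn, k_a, fab_min, fab_max, tau_p, tau_z, h_car;
  double fes_inf, fes0, k_es, fes_min, fev0, fev_inf, k_ev, fab0;
  double g_cp, Pcv_n, cp_cap, tau_cp;
  double gR_up, gR_sp, gR_kp, gR_lb;
  double gVu, gE, gTs, gTv;
  double tau_R, tau_Vu, tau_E, tau_T, D_s, D_v, kD;
  double k_myo, Ptm_ref;
  double T_base;
  // derived baselines
  double fab_b, fes_b, fev_b, x0;
  double R0_up, R0_sp, R0_kp, R0_lb, Vu0_uv, Vu0_sv, Vu0_kv, Vu0_lbv, E0_lv, E0_rv;
};

static double getp(const NumericVector& p, const char* nm) {
  NumericVector::const_iterator it;
  CharacterVector nms = p.names();
  for (int i = 0; i < p.size(); ++i)
    if (std::strcmp(CHAR(STRING_ELT(nms, i)), nm) == 0) return p[i];
  stop(std::string("missing parameter: ") + nm);
  return NA_REAL;
}

static void fill_pars(const NumericVector& p, Pars& P) {
  const char* ch[5] = {"lvf", "rvf", "spt", "la", "ra"};
  Ch* tgt[5] = {&P.lvf, &P.rvf, &P.spt, &P.la, &P.ra};
  for (int c = 0; c < 5; ++c) {
    std::string b = std::string("heart.") + ch[c] + ".";
    tgt[c]->Ees = getp(p, (b + "Ees").c_str());
    tgt[c]->V0  = getp(p, (b + "V0").c_str());
    tgt[c]->P0  = getp(p, (b + "P0").c_str());
    tgt[c]->lam = getp(p, (b + "lam").c_str());
  }
  P.peri_P0 = getp(p, "heart.peri.P0");
  P.peri_lam = getp(p, "heart.peri.lam");
  P.peri_V0 = getp(p, "heart.peri.V0");
  P.Vmyo = getp(p, "heart.peri.Vmyo");
  P.peri_dynamic = getp(p, "heart.peri.dynamic") > 0.5 ? 1 : 0;
  P.peri_frozen = getp(p, "heart.peri.frozen_P");
  P.s_sys_v = getp(p, "heart.act.s_sys_v");
  P.atr_off = getp(p, "heart.act.atrial_offset");
  P.d_a = getp(p, "heart.act.d_a");
  P.Rmt = getp(p, "heart.mt.R"); P.Lmt = getp(p, "heart.mt.L");
  P.Rav = getp(p, "heart.av.R"); P.Lav = getp(p, "heart.av.L");
  P.Rtc = getp(p, "heart.tc.R"); P.Ltc = getp(p, "heart.tc.L");
  P.Rpv = getp(p, "heart.pv.R"); P.Lpv = getp(p, "heart.pv.L");
  double rho = getp(p, "circ.env.rho"), g = getp(p, "circ.env.g");
  P.khyd = rho * g * 0.01 / 133.322;   // cm column -> mmHg
  P.collapse_k = getp(p, "circ.env.collapse_k");
  P.C_sa = getp(p, "circ.sa.C"); P.Vu_sa = getp(p, "circ.sa.Vu");
  P.C_tv = getp(p, "circ.tv.C"); P.Vu_tv = getp(p, "circ.tv.Vu");
  P.R_tv = getp(p, "circ.tv.R");
  const char* br[6] = {"b", "u", "h", "s", "k", "lb"};
  for (int i = 0; i < 6; ++i) {
    std::string b = std::string("circ.") + br[i] + ".";
    P.Cp[i]  = getp(p, (b + "C_p").c_str());
    P.Vup[i] = getp(p, (b + "Vu_p").c_str());
    P.Cv[i]  = getp(p, (b + "C_v").c_str());
    P.Vuv[i] = getp(p, (b + "Vu_v").c_str());
    P.Ra[i]  = getp(p, (b + "R_a").c_str());
    P.Rm[i]  = getp(p, (b + "R_m").c_str());
    P.Rv[i]  = getp(p, (b + "R_v").c_str());
    P.hh[i]  = getp(p, (b + "h").c_str());
  }
  P.Vmax_lb = getp(p, "circ.lb.Vmax");
  P.sP_dist = getp(p, "circ.s.P_dist");
  P.s_kdist = getp(p, "circ.s.k_dist");
  P.C_pa = getp(p, "circ.pul.C_pa"); P.Vu_pa = getp(p, "circ.pul.Vu_pa");
  P.R_pa = getp(p, "circ.pul.R_pa");
  P.C_pc = getp(p, "circ.pul.C_pc"); P.Vu_pc = getp(p, "circ.pul.Vu_pc");
  P.R_pc = getp(p, "circ.pul.R_pc");
  P.C_pu = getp(p, "circ.pul.C_pu"); P.Vu_pu = getp(p, "circ.pul.Vu_pu");
  P.R_pu = getp(p, "circ.pul.R_pu");
  P.Pn = getp(p, "reflex.afferent.Pn");
  P.k_a = getp(p, "reflex.afferent.k_a");
  P.fab_min = getp(p, "reflex.afferent.f_min");
  P.fab_max = getp(p, "reflex.afferent.f_max");
  P.tau_p = getp(p, "reflex.afferent.tau_p");
  P.tau_z = getp(p, "reflex.afferent.tau_z");
  P.h_car = getp(p, "reflex.afferent.h_carotid");
  P.fes_inf = getp(p, "reflex.efferent.fes_inf");
  P.fes0 = getp(p, "reflex.efferent.fes_0");
  P.k_es = getp(p, "reflex.efferent.k_es");
  P.fes_min = getp(p, "reflex.efferent.fes_min");
  P.fev0 = getp(p, "reflex.efferent.fev_0");
  P.fev_inf = getp(p, "reflex.efferent.fev_inf");
  P.k_ev = getp(p, "reflex.efferent.k_ev");
  P.fab0 = getp(p, "reflex.efferent.fab_0");
  P.g_cp = getp(p, "reflex.cp.gain");
  P.Pcv_n = getp(p, "reflex.cp.Pcv_n");
  P.cp_cap = getp(p, "reflex.cp.cap");
  P.tau_cp = getp(p, "reflex.cp.tau");
  P.gR_up = getp(p, "reflex.eff.gR_up");
  P.gR_sp = getp(p, "reflex.eff.gR_sp");
  P.gR_kp = getp(p, "reflex.eff.gR_kp");
  P.gR_lb = getp(p, "reflex.eff.gR_lb");
  P.gVu = getp(p, "reflex.eff.gVu");
  P.gE = getp(p, "reflex.eff.gE");
  P.gTs = getp(p, "reflex.eff.gTs");
  P.gTv = getp(p, "reflex.eff.gTv");
  P.tau_R = getp(p, "reflex.eff.tau_R");
  P.tau_Vu = getp(p, "reflex.eff.tau_Vu");
  P.tau_E = getp(p, "reflex.eff.tau_E");
  P.tau_T = getp(p, "reflex.eff.tau_T");
  P.D_s = getp(p, "reflex.eff.D_s");
  P.D_v = getp(p, "reflex.eff.D_v");
  P.kD = getp(p, "reflex.eff.kD");
  P.k_myo = getp(p, "reflex.myo.k_myo");
  P.Ptm_ref = getp(p, "reflex.myo.Ptm_ref");
  P.T_base = getp(p, "reflex.T_base");
  if (P.T_base <= 0) stop("invalid parameter: reflex.T_base must be > 0");
  // baseline operating point of the reflex arcs: either the calibrated
  // supine mean drives (reference parameters) or, as fallback, the static
  // values at the afferent set-point
  P.fab_b = 0.5 * (P.fab_min + P.fab_max);
  P.fes_b = P.fes_inf + (P.fes0 - P.fes_inf) * std::exp(-P.k_es * P.fab_b);
  double ee = std::exp((P.fab_b - P.fab0) / P.k_ev);
  P.fev_b = (P.fev0 + P.fev_inf * ee) / (1.0 + ee);
  P.x0 = std::log(P.fes_b - P.fes_min + 1.0);
  double xr = getp(p, "reflex.eff.x_ref");
  double fr = getp(p, "reflex.eff.fev_ref");
  if (xr > -900.0) P.x0 = xr;
  if (fr > -900.0) P.fev_b = fr;
  P.R0_up = P.Ra[1]; P.R0_sp = P.Ra[3]; P.R0_kp = P.Ra[4]; P.R0_lb = P.Ra[5];
  P.Vu0_uv = P.Vuv[1]; P.Vu0_sv = P.Vuv[3]; P.Vu0_kv = P.Vuv[4];
  P.Vu0_lbv = P.Vuv[5];
  P.E0_lv = P.lvf.Ees; P.E0_rv = P.rvf.Ees;
}

static inline double chP(const Ch& c, double V, double e) {
  return e * c.Ees * (V - c.V0) + (1.0 - e) * c.P0 * expm1(c.lam * (V - c.V0));
}
static inline double chdP(const Ch& c, double V, double e) {
  return e * c.Ees + (1.0 - e) * c.P0 * c.lam * std::exp(c.lam * (V - c.V0));
}

// periodic raised-cosine activation lobe: peak 1 at x = dur/2, exactly 0
// outside [0, dur) -- a broad systolic plateau and a clean diastole
static inline double act(double x, double dur) {
  x -= std::floor(x);
  if (x >= dur) return 0.0;
  return 0.5 * (1.0 - std::cos(2.0 * M_PI * x / dur));
}

// lower-body venous capacity law: dP/dV = 1/C0 at Vu, P -> inf as V -> Vmax
static inline double lbv_P(double V, double Vu, double Vmax, double C0) {
  double cap = Vmax - Vu;
  double x = (V - Vu) / cap;
  if (x <= 0.0) return (V - Vu) / C0;
  const double xc = 0.99;
  if (x < xc) return (2.0 * cap / (M_PI * C0)) * std::tan(M_PI * x / 2.0);
  double Pc = (2.0 * cap / (M_PI * C0)) * std::tan(M_PI * xc / 2.0);
  double cs = std::cos(M_PI * xc / 2.0);
  double dc = 1.0 / (C0 * cs * cs);
  return Pc + dc * (V - (Vu + xc * cap));
}

static double solve_septum(const Pars& P, double Vlv, double Vrv, double e,
                           double guess, int* err) {
  double Vs = guess;
  for (int it = 0; it < 60; ++it) {
    double r = chP(P.spt, Vs, e) - chP(P.lvf, Vlv - Vs, e) + chP(P.rvf, Vrv + Vs, e);
    if (std::fabs(r) < 1e-10) { if (err) *err = 0; return Vs; }
    double dr = chdP(P.spt, Vs, e) + chdP(P.lvf, Vlv - Vs, e) + chdP(P.rvf, Vrv + Vs, e);
    double step = r / dr;
    if (step > 20.0) step = 20.0; if (step < -20.0) step = -20.0;
    Vs -= step;
  }
  if (err) *err = 1;
  return Vs;
}

struct Aux {
  double e_v, e_a, Vspt, Pperi;
  double Plv, Prv, Pla, Pra;
  double Psa, Ptv, Ppa, Ppc, Ppu;
  double Ptm_p[6], Ptm_v[6];
  double Q1[6], Q3[6];
  double fab, fes, fev, xs, cpdev;
  double R_lb_eff;
};

static void rhs(const Pars& P, const double* y, double s, double Tb,
                double sina, double xd, double fevd, double cpd,
                double* dy, Aux& A, double* spt_guess) {
  s -= std::floor(s);
  A.e_v = act(s, P.s_sys_v);
  // atrial systole peaks atr_off of a beat before ventricular onset
  A.e_a = act(s - (1.0 - P.atr_off - 0.5 * P.d_a), P.d_a);

  int serr = 0;
  A.Vspt = solve_septum(P, y[iVlv], y[iVrv], A.e_v, *spt_guess, &serr);
  *spt_guess = A.Vspt;

  // pericardial sac encloses the ventricles and myocardium; the atria sit
  // outside and couple to the ventricles only through the circulation
  double Vpcd = y[iVlv] + y[iVrv] + P.Vmyo;
  A.Pperi = P.peri_dynamic
    ? P.peri_P0 * expm1(P.peri_lam * (Vpcd - P.peri_V0))
    : P.peri_frozen;

  A.Plv = chP(P.lvf, y[iVlv] - A.Vspt, A.e_v) + A.Pperi;
  A.Prv = chP(P.rvf, y[iVrv] + A.Vspt, A.e_v) + A.Pperi;
  A.Pla = chP(P.la, y[iVla], A.e_a);
  A.Pra = chP(P.ra, y[iVra], A.e_a);

  A.Psa = (y[iVsa] - P.Vu_sa) / P.C_sa;
  A.Ptv = (y[iVtv] - P.Vu_tv) / P.C_tv;
  A.Ppa = (y[iVpa] - P.Vu_pa) / P.C_pa;
  A.Ppc = (y[iVpc] - P.Vu_pc) / P.C_pc;
  A.Ppu = (y[iVpu] - P.Vu_pu) / P.C_pu;

  // branch node pressures: transmural (V-Vu)/C; flow nodes heart-referenced
  double Vu_v_cur[6] = {P.Vuv[0], y[iVuuv], P.Vuv[2], y[iVusv], y[iVukv], y[iVulbv]};
  double Pn_p[6], Pn_v[6];
  for (int i = 0; i < 6; ++i) {
    A.Ptm_p[i] = (y[iVbp + 2 * i] - P.Vup[i]) / P.Cp[i];
    if (A.Ptm_p[i] < 0.0) A.Ptm_p[i] *= P.collapse_k;   // vessel collapse
    if (i == 5)
      A.Ptm_v[i] = lbv_P(y[iVbv + 2 * i], Vu_v_cur[i], P.Vmax_lb, P.Cv[i]);
    else {
      A.Ptm_v[i] = (y[iVbv + 2 * i] - Vu_v_cur[i]) / P.Cv[i];
      if (A.Ptm_v[i] < 0.0) A.Ptm_v[i] *= P.collapse_k;
      if (i == 3 && A.Ptm_v[i] > P.sP_dist)   // distension stiffening
        A.Ptm_v[i] = P.sP_dist + (A.Ptm_v[i] - P.sP_dist) * P.s_kdist;
    }
    double Ph = P.khyd * P.hh[i] * sina;
    Pn_p[i] = A.Ptm_p[i] - Ph;
    Pn_v[i] = A.Ptm_v[i] - Ph;
  }

  // myogenic autoregulation on the lower-body arterial resistance
  double myof = 1.0 + P.k_myo * (A.Ptm_p[5] - P.Ptm_ref);
  if (myof < 0.2) myof = 0.2;
  A.R_lb_eff = y[iRlb] * myof;
  if (A.R_lb_eff < 0.2 * P.R0_lb) A.R_lb_eff = 0.2 * P.R0_lb;
  if (A.R_lb_eff > 8.0 * P.R0_lb) A.R_lb_eff = 8.0 * P.R0_lb;

  double Rin[6] = {P.Ra[0], y[iRup], P.Ra[2], y[iRsp], y[iRkp], A.R_lb_eff};
  double Q2[6];
  for (int i = 0; i < 6; ++i) {
    A.Q1[i] = (A.Psa - Pn_p[i]) / Rin[i];
    Q2[i] = (Pn_p[i] - Pn_v[i]) / P.Rm[i];
    double q3 = (Pn_v[i] - A.Ptv) / P.Rv[i];
    A.Q3[i] = q3 > 0.0 ? q3 : 0.0;           // venous valve (ideal diode)
  }
  double Qtvra = (A.Ptv - A.Pra) / P.R_tv;
  double Qpa = (A.Ppa - A.Ppc) / P.R_pa;
  double Qpc = (A.Ppc - A.Ppu) / P.R_pc;
  double Qpu = (A.Ppu - A.Pla) / P.R_pu;

  // heart valves: flow states with inertance; closed while Q<=0 and dP<=0
  double dpmt = A.Pla - A.Plv, dpav = A.Plv - A.Psa;
  double dptc = A.Pra - A.Prv, dppv = A.Prv - A.Ppa;
  double q, Qmt, Qav, Qtc, Qpv;
  q = y[iQmt];
  dy[iQmt] = (q > 1e-9 || dpmt > 0.0) ? (dpmt - P.Rmt * q) / P.Lmt : 0.0;
  Qmt = q > 0.0 ? q : 0.0;
  q = y[iQav];
  dy[iQav] = (q > 1e-9 || dpav > 0.0) ? (dpav - P.Rav * q) / P.Lav : 0.0;
  Qav = q > 0.0 ? q : 0.0;
  q = y[iQtc];
  dy[iQtc] = (q > 1e-9 || dptc > 0.0) ? (dptc - P.Rtc * q) / P.Ltc : 0.0;
  Qtc = q > 0.0 ? q : 0.0;
  q = y[iQpv];
  dy[iQpv] = (q > 1e-9 || dppv > 0.0) ? (dppv - P.Rpv * q) / P.Lpv : 0.0;
  Qpv = q > 0.0 ? q : 0.0;

  // volume conservation
  double sumQ1 = 0.0, sumQ3 = 0.0;
  for (int i = 0; i < 6; ++i) { sumQ1 += A.Q1[i]; sumQ3 += A.Q3[i]; }
  dy[iVlv] = Qmt - Qav;
  dy[iVrv] = Qtc - Qpv;
  dy[iVla] = Qpu - Qmt;
  dy[iVra] = Qtvra - Qtc;
  dy[iVsa] = Qav - sumQ1;
  for (int i = 0; i < 6; ++i) {
    dy[iVbp + 2 * i] = A.Q1[i] - Q2[i];
    dy[iVbv + 2 * i] = Q2[i] - A.Q3[i];
  }
  dy[iVtv] = sumQ3 - Qtvra;
  dy[iVpa] = Qpv - Qpa;
  dy[iVpc] = Qpa - Qpc;
  dy[iVpu] = Qpc - Qpu;

  // afferent arterial pathway: carotid column, pole/zero block, sigmoid
  double u = A.Psa - P.khyd * P.h_car * sina;
  double du = dy[iVsa] / P.C_sa;
  dy[iPtl] = (u + P.tau_z * du - y[iPtl]) / P.tau_p;
  double z = (y[iPtl] - P.Pn) / P.k_a;
  double lg = z > 0 ? 1.0 / (1.0 + std::exp(-z)) : std::exp(z) / (1.0 + std::exp(z));
  A.fab = P.fab_min + (P.fab_max - P.fab_min) * lg;
  A.fes = P.fes_inf + (P.fes0 - P.fes_inf) * std::exp(-P.k_es * A.fab);
  double ev = std::exp((A.fab - P.fab0) / P.k_ev);
  A.fev = (P.fev0 + P.fev_inf * ev) / (1.0 + ev);
  double xarg = A.fes - P.fes_min + 1.0;
  A.xs = std::log(xarg > 1e-6 ? xarg : 1e-6);

  // cardiopulmonary pathway: low-pass on central venous pressure,
  // bounded linear deviation feeding the resistance effectors only
  dy[iPcvf] = (A.Ptv - y[iPcvf]) / P.tau_cp;
  double cd = P.g_cp * (P.Pcv_n - y[iPcvf]);
  if (cd > P.cp_cap) cd = P.cp_cap;
  if (cd < -P.cp_cap) cd = -P.cp_cap;
  A.cpdev = cd;

  // effectors: first-order with delayed drives; desensitization divides gains
  double dx = xd - P.x0;
  double kD = P.kD;
  double sig;
  sig = P.R0_up * (1.0 + (P.gR_up * dx + cpd) / kD);
  if (sig < 0.2 * P.R0_up) sig = 0.2 * P.R0_up;
  if (sig > 5.0 * P.R0_up) sig = 5.0 * P.R0_up;
  dy[iRup] = (sig - y[iRup]) / P.tau_R;
  sig = P.R0_sp * (1.0 + (P.gR_sp * dx + cpd) / kD);
  if (sig < 0.2 * P.R0_sp) sig = 0.2 * P.R0_sp;
  if (sig > 5.0 * P.R0_sp) sig = 5.0 * P.R0_sp;
  dy[iRsp] = (sig - y[iRsp]) / P.tau_R;
  sig = P.R0_kp * (1.0 + (P.gR_kp * dx + cpd) / kD);
  if (sig < 0.2 * P.R0_kp) sig = 0.2 * P.R0_kp;
  if (sig > 5.0 * P.R0_kp) sig = 5.0 * P.R0_kp;
  dy[iRkp] = (sig - y[iRkp]) / P.tau_R;
  sig = P.R0_lb * (1.0 + (P.gR_lb * dx + cpd) / kD);
  if (sig < 0.2 * P.R0_lb) sig = 0.2 * P.R0_lb;
  if (sig > 5.0 * P.R0_lb) sig = 5.0 * P.R0_lb;
  dy[iRlb] = (sig - y[iRlb]) / P.tau_R;

  double vu0[4] = {P.Vu0_uv, P.Vu0_sv, P.Vu0_kv, P.Vu0_lbv};
  for (int j = 0; j < 4; ++j) {
    sig = vu0[j] * (1.0 + P.gVu * dx / kD);
    if (sig < 0.4 * vu0[j]) sig = 0.4 * vu0[j];
    if (sig > 1.5 * vu0[j]) sig = 1.5 * vu0[j];
    dy[iVuuv + j] = (sig - y[iVuuv + j]) / P.tau_Vu;
  }
  sig = P.E0_lv * (1.0 + P.gE * dx / kD);
  if (sig < 0.2 * P.E0_lv) sig = 0.2 * P.E0_lv;
  if (sig > 5.0 * P.E0_lv) sig = 5.0 * P.E0_lv;
  dy[iElv] = (sig - y[iElv]) / P.tau_E;
  sig = P.E0_rv * (1.0 + P.gE * dx / kD);
  if (sig < 0.2 * P.E0_rv) sig = 0.2 * P.E0_rv;
  if (sig > 5.0 * P.E0_rv) sig = 5.0 * P.E0_rv;
  dy[iErv] = (sig - y[iErv]) / P.tau_E;
  // desensitization degrades the sympathetic static characteristics;
  // vagal control of the heart period keeps its full gain
  sig = P.T_base * (1.0 + P.gTs * dx / kD + P.gTv * (fevd - P.fev_b));
  if (sig < 0.4 * P.T_base) sig = 0.4 * P.T_base;
  if (sig > 2.5 * P.T_base) sig = 2.5 * P.T_base;
  dy[iTef] = (sig - y[iTef]) / P.tau_T;
}

// piecewise sin(alpha) with linear ramps between protocol segments
struct Tilt {
  std::vector<double> t0, sina;
  double ramp;
  double at(double t) const {
    size_t n = t0.size();
    size_t j = 0;
    while (j + 1 < n && t >= t0[j + 1]) ++j;
    double s1 = sina[j];
    if (j == 0 || ramp <= 0.0) return s1;
    double dt = t - t0[j];
    if (dt >= ramp) return s1;
    double s0 = sina[j - 1];
    return s0 + (s1 - s0) * dt / ramp;
  }
};

static const char* beat_cols[] = {
  "t_start", "T", "HR", "MAP", "P_la", "P_pa", "P_cv", "P_pu", "P_peri",
  "LV_EDV", "LV_ESV", "RV_EDV", "RV_ESV", "SV", "SV_flow", "CO",
  "V_thoracic", "V_upper", "V_splanchnic", "V_renal", "V_lower",
  "V_cerebral", "V_coronary", "V_total",
  "Q_cerebral", "Q_upper", "Q_coronary", "Q_splanchnic", "Q_renal", "Q_lower",
  "R_up", "R_sp", "R_kp", "R_lb", "Vu_sv", "E_lv", "E_rv", "f_ab", "alpha"
};
static const int NBC = 39;

static const char* ser_cols[] = {
  "t", "alpha", "P_lv", "P_rv", "P_la", "P_ra", "P_sa", "P_pa", "P_pc",
  "P_pu", "P_tv", "P_peri", "Q_mt", "Q_av", "Q_tc", "Q_pv", "e_v", "V_spt",
  "V_lv", "V_rv", "V_la", "V_ra", "V_sa", "V_bp", "V_bv", "V_up", "V_uv",
  "V_hp", "V_hv", "V_sp", "V_sv", "V_kp", "V_kv", "V_lbp", "V_lbv", "V_tv",
  "V_pa", "V_pc", "V_pu", "f_ab", "f_es", "f_ev", "R_lb_eff", "T_eff",
  "Q_lb_in", "V_total"
};
static const int NSC = 46;

// [[Rcpp::export]]
List cvs_core_simulate(NumericVector pars, NumericMatrix protocol, List options) {
  Pars P;
  fill_pars(pars, P);
  double dt = as<double>(options["dt"]);
  double out_dt = as<double>(options["out_dt"]);
  double ramp = as<double>(options["ramp_time"]);
  bool record = as<bool>(options["record"]);
  NumericVector y0 = as<NumericVector>(options["init_state"]);
  double T_beat = as<double>(options["init_T"]);
  double t_in_beat = as<double>(options["init_phase"]);
  if (y0.size() != NST) stop("init_state must have length %d", NST);
  if (dt <= 0) stop("invalid dt");
  if (T_beat <= 0) stop("invalid heart period: T must be > 0");

  Tilt tl; tl.ramp = ramp;
  double ttot = 0.0;
  for (int i = 0; i < protocol.nrow(); ++i) {
    double a = protocol(i, 0);
    if (a < 0 || a > 90) stop("tilt angle outside [0, 90]");
    tl.t0.push_back(ttot);
    tl.sina.push_back(std::sin(a * M_PI / 180.0));
    ttot += protocol(i, 1);
  }
  long nsteps = (long)std::ceil(ttot / dt - 1e-9);
  int out_every = (int)std::max(1.0, std::round(out_dt / dt));

  std::vector<double> y(y0.begin(), y0.end());
  double spt_guess = 0.0;

  // delay ring buffers for the efferent drives
  int nDs = (int)std::round(P.D_s / dt), nDv = (int)std::round(P.D_v / dt);
  int nbuf = std::max(std::max(nDs, nDv), 1) + 2;
  std::vector<double> xbuf(nbuf, P.x0), evbuf(nbuf, P.fev_b), cpbuf(nbuf, 0.0);
  {
    // seed buffers from the initial state's drives
    Aux A0; double d0[NST];
    rhs(P, y.data(), t_in_beat / T_beat, T_beat, tl.at(0.0),
        P.x0, P.fev_b, 0.0, d0, A0, &spt_guess);
    std::fill(xbuf.begin(), xbuf.end(), A0.xs);
    std::fill(evbuf.begin(), evbuf.end(), A0.fev);
    std::fill(cpbuf.begin(), cpbuf.end(), A0.cpdev);
  }

  long max_out = record ? (nsteps / out_every + 2) : 1;
  NumericMatrix series(record ? max_out : 1, NSC);
  long nout = 0;

  std::vector<double> beats;
  beats.reserve(512 * NBC);

  // per-beat accumulators
  double acc[NBC]; std::fill(acc, acc + NBC, 0.0);
  double acc_t = 0.0, beat_t0 = 0.0;
  double lv_min = y[iVlv], lv_max = y[iVlv], rv_min = y[iVrv], rv_max = y[iVrv];
  double qav_int = 0.0;

  double k1[NST], k2[NST], k3[NST], k4[NST], yt[NST];
  Aux A1, At;
  double t = 0.0;
  long step = 0;
  int bad_state = -1;

  for (step = 0; step < nsteps; ++step) {
    double sina = tl.at(t);
    int ib = (int)(step % nbuf);
    double xd = xbuf[(ib - nDs % nbuf + nbuf) % nbuf];
    double fevd = evbuf[(ib - nDv % nbuf + nbuf) % nbuf];
    double cpd = cpbuf[(ib - nDs % nbuf + nbuf) % nbuf];

    rhs(P, y.data(), t_in_beat / T_beat, T_beat, sina, xd, fevd, cpd, k1, A1, &spt_guess);

    // push current drives
    xbuf[ib] = A1.xs; evbuf[ib] = A1.fev; cpbuf[ib] = A1.cpdev;

    if (record && step % out_every == 0 && nout < max_out) {
      double* row = &series(nout, 0);
      // matrix is column-major; fill via () accessor instead
      series(nout, 0) = t; series(nout, 1) = std::asin(sina) * 180.0 / M_PI;
      series(nout, 2) = A1.Plv; series(nout, 3) = A1.Prv;
      series(nout, 4) = A1.Pla; series(nout, 5) = A1.Pra;
      series(nout, 6) = A1.Psa; series(nout, 7) = A1.Ppa;
      series(nout, 8) = A1.Ppc; series(nout, 9) = A1.Ppu;
      series(nout, 10) = A1.Ptv; series(nout, 11) = A1.Pperi;
      series(nout, 12) = y[iQmt] > 0 ? y[iQmt] : 0;
      series(nout, 13) = y[iQav] > 0 ? y[iQav] : 0;
      series(nout, 14) = y[iQtc] > 0 ? y[iQtc] : 0;
      series(nout, 15) = y[iQpv] > 0 ? y[iQpv] : 0;
      series(nout, 16) = A1.e_v; series(nout, 17) = A1.Vspt;
      for (int v = 0; v < 21; ++v) series(nout, 18 + v) = y[v];
      series(nout, 39) = A1.fab; series(nout, 40) = A1.fes;
      series(nout, 41) = A1.fev; series(nout, 42) = A1.R_lb_eff;
      series(nout, 43) = y[iTef]; series(nout, 44) = A1.Q1[5];
      double vt = 0.0; for (int v = 0; v < 21; ++v) vt += y[v];
      series(nout, 45) = vt;
      (void)row;
      ++nout;
    }

    // beat accumulation (rectangle rule on the step-start evaluation)
    acc[3] += A1.Psa * dt; acc[4] += A1.Pla * dt; acc[5] += A1.Ppa * dt;
    acc[6] += A1.Ptv * dt; acc[7] += A1.Ppu * dt; acc[8] += A1.Pperi * dt;
    double vthor = y[iVlv] + y[iVrv] + y[iVla] + y[iVra] + y[iVpa] + y[iVpc] + y[iVpu];
    acc[16] += vthor * dt;
    acc[17] += (y[iVup] + y[iVuv]) * dt;
    acc[18] += (y[iVsp] + y[iVsv]) * dt;
    acc[19] += (y[iVkp] + y[iVkv]) * dt;
    acc[20] += (y[iVlbp] + y[iVlbv]) * dt;
    acc[21] += (y[iVbp] + y[iVbv]) * dt;
    acc[22] += (y[iVhp] + y[iVhv]) * dt;
    double vt = 0.0; for (int v = 0; v < 21; ++v) vt += y[v];
    acc[23] += vt * dt;
    acc[24] += A1.Q1[0] * dt; acc[25] += A1.Q1[1] * dt; acc[26] += A1.Q1[2] * dt;
    acc[27] += A1.Q1[3] * dt; acc[28] += A1.Q1[4] * dt; acc[29] += A1.Q1[5] * dt;
    acc[30] += y[iRup] * dt; acc[31] += y[iRsp] * dt; acc[32] += y[iRkp] * dt;
    acc[33] += A1.R_lb_eff * dt; acc[34] += y[iVusv] * dt;
    acc[35] += y[iElv] * dt; acc[36] += y[iErv] * dt; acc[37] += A1.fab * dt;
    acc[38] += std::asin(sina) * 180.0 / M_PI * dt;
    qav_int += (y[iQav] > 0 ? y[iQav] : 0) * dt;
    acc_t += dt;

    // RK4
    for (int i = 0; i < NST; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    rhs(P, yt, (t_in_beat + 0.5 * dt) / T_beat, T_beat, tl.at(t + 0.5 * dt), xd, fevd, cpd, k2, At, &spt_guess);
    for (int i = 0; i < NST; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    rhs(P, yt, (t_in_beat + 0.5 * dt) / T_beat, T_beat, tl.at(t + 0.5 * dt), xd, fevd, cpd, k3, At, &spt_guess);
    for (int i = 0; i < NST; ++i) yt[i] = y[i] + dt * k3[i];
    rhs(P, yt, (t_in_beat + dt) / T_beat, T_beat, tl.at(t + dt), xd, fevd, cpd, k4, At, &spt_guess);
    for (int i = 0; i < NST; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    // valve closure: clamp flow states at zero crossing
    for (int v = iQmt; v <= iQpv; ++v) if (y[v] < 0.0) y[v] = 0.0;

    if (step % 200 == 0) {
      for (int i = 0; i < NST; ++i)
        if (!std::isfinite(y[i])) { bad_state = i; break; }
      if (bad_state >= 0) break;
    }

    if (y[iVlv] < lv_min) lv_min = y[iVlv];
    if (y[iVlv] > lv_max) lv_max = y[iVlv];
    if (y[iVrv] < rv_min) rv_min = y[iVrv];
    if (y[iVrv] > rv_max) rv_max = y[iVrv];

    t += dt; t_in_beat += dt;

    if (t_in_beat >= T_beat - 1e-12) {
      // finalize beat
      double row[NBC];
      row[0] = beat_t0; row[1] = T_beat; row[2] = 60.0 / T_beat;
      for (int c = 3; c < NBC; ++c) row[c] = acc[c] / acc_t;
      row[9] = lv_max; row[10] = lv_min; row[11] = rv_max; row[12] = rv_min;
      row[13] = lv_max - lv_min; row[14] = qav_int;
      row[15] = (lv_max - lv_min) * (60.0 / T_beat) / 1000.0;
      for (int c = 0; c < NBC; ++c) beats.push_back(row[c]);
      std::fill(acc, acc + NBC, 0.0);
      acc_t = 0.0; qav_int = 0.0; beat_t0 = t;
      lv_min = lv_max = y[iVlv]; rv_min = rv_max = y[iVrv];
      t_in_beat -= T_beat;
      double Tn = y[iTef];
      if (Tn < 0.3) Tn = 0.3; if (Tn > 3.0) Tn = 3.0;
      T_beat = Tn;
    }
  }

  if (bad_state >= 0) {
    stop("numeric failure: non-finite value in state %d at t = %.3f s",
         bad_state + 1, t);
  }

  long nbeats = (long)(beats.size() / NBC);
  NumericMatrix bm(nbeats, NBC);
  for (long b = 0; b < nbeats; ++b)
    for (int c = 0; c < NBC; ++c) bm(b, c) = beats[b * NBC + c];
  CharacterVector bnm(NBC);
  for (int c = 0; c < NBC; ++c) bnm[c] = beat_cols[c];
  colnames(bm) = bnm;

  List out = List::create(
    _["beats"] = bm,
    _["final_state"] = NumericVector(y.begin(), y.end()),
    _["final_T"] = T_beat,
    _["final_phase"] = t_in_beat,
    _["duration"] = ttot);
  if (record) {
    NumericMatrix sm(nout, NSC);
    for (long r = 0; r < nout; ++r)
      for (int c = 0; c < NSC; ++c) sm(r, c) = series(r, c);
    CharacterVector snm(NSC);
    for (int c = 0; c < NSC; ++c) snm[c] = ser_cols[c];
    colnames(sm) = snm;
    out["series"] = sm;
  }
  return out;
}

// single derivative evaluation for diagnostics / Jacobian checks
// [[Rcpp::export]]
List cvs_core_rhs(NumericVector pars, NumericVector state, double phase,
                  double T_beat, double alpha) {
  Pars P;
  fill_pars(pars, P);
  if (state.size() != NST) stop("state must have length %d", NST);
  if (T_beat <= 0) stop("invalid heart period: T must be > 0");
  double y[NST], dy[NST];
  for (int i = 0; i < NST; ++i) y[i] = state[i];
  Aux A;
  double guess = 0.0;
  double sina = std::sin(alpha * M_PI / 180.0);
  rhs(P, y, phase, T_beat, sina, A.xs = P.x0, P.fev_b, 0.0, dy, A, &guess);
  for (int i = 0; i < NST; ++i)
    if (!std::isfinite(dy[i]))
      stop("numeric failure: non-finite derivative in state %d", i + 1);
  return List::create(
    _["deriv"] = NumericVector(dy, dy + NST),
    _["aux"] = List::create(
      _["e_v"] = A.e_v, _["e_a"] = A.e_a, _["V_spt"] = A.Vspt,
      _["P_peri"] = A.Pperi, _["P_lv"] = A.Plv, _["P_rv"] = A.Prv,
      _["P_la"] = A.Pla, _["P_ra"] = A.Pra, _["P_sa"] = A.Psa,
      _["P_tv"] = A.Ptv, _["P_pa"] = A.Ppa, _["P_pu"] = A.Ppu,
      _["f_ab"] = A.fab, _["f_es"] = A.fes, _["f_ev"] = A.fev,
      _["R_lb_eff"] = A.R_lb_eff));
}

// [[Rcpp::export]]
double cvs_core_septum(NumericVector pars, double Vlv, double Vrv, double e) {
  Pars P;
  fill_pars(pars, P);
  int err = 0;
  double v = solve_septum(P, Vlv, Vrv, e, 0.0, &err);
  if (err) stop("septum solve did not converge (Vlv=%.2f, Vrv=%.2f, e=%.3f)", Vlv, Vrv, e);
  return v;
}
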