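// Compiled core of the coupled 1-D haemodynamics / myogenic wall solver.
//
// Units are CGS throughout (cm, g, s, dyn/cm^2); pressures cross the
// signalling interface in mmHg. The R sources implement the same elementary
// operations as reference; the test suite cross-checks both paths.

#include <RcppArmadillo.h>
#include <ctime>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double MMHG = 1333.22387415;

// ---------------------------------------------------------------------------
// Parameter and geometry bundles
// ---------------------------------------------------------------------------

struct Pars {
  double link_slope[9], link_half[9];
  int link_inv[9], link_input[9]; // 0 = pressure (mmHg), 1..7 = xi0..xi6
  double tau_c;
  int calcium_mode; // 0 control, 1 diltiazem, 2 zero_ca
  double dilt_scale, dilt_slope, dilt_half;
  double Lm, dm, nXB, kXB, uPS, NCU, sf0, ufs_opt, NCF, kACmax, nAC, KAC;
  double c0, c1, c2, phi;
  double rho, mu;
  double tau_m, Pext;
  int wall_mode; // 0 active, 1 passive, 2 rigid
};

static Pars read_pars(const List& pl) {
  Pars p;
  NumericVector ls = pl["link_slope"], lh = pl["link_half"];
  IntegerVector li = pl["link_inv"], lc = pl["link_input"];
  for (int j = 0; j < 9; j++) {
    p.link_slope[j] = ls[j]; p.link_half[j] = lh[j];
    p.link_inv[j] = li[j]; p.link_input[j] = lc[j];
  }
  p.tau_c = pl["tau_c"]; p.calcium_mode = as<int>(pl["calcium_mode"]);
  p.dilt_scale = pl["dilt_scale"]; p.dilt_slope = pl["dilt_slope"];
  p.dilt_half = pl["dilt_half"];
  p.Lm = pl["Lm"]; p.dm = pl["dm"]; p.nXB = pl["nXB"]; p.kXB = pl["kXB"];
  p.uPS = pl["uPS"]; p.NCU = pl["NCU"]; p.sf0 = pl["sf0"];
  p.ufs_opt = pl["ufs_opt"]; p.NCF = pl["NCF"]; p.kACmax = pl["kACmax"];
  p.nAC = pl["nAC"]; p.KAC = pl["KAC"];
  p.c0 = pl["c0"]; p.c1 = pl["c1"]; p.c2 = pl["c2"]; p.phi = pl["phi"];
  p.rho = pl["rho"]; p.mu = pl["mu"];
  p.tau_m = pl["tau_m"]; p.Pext = pl["Pext"];
  p.wall_mode = as<int>(pl["wall_mode"]);
  return p;
}

struct Geom {
  double Ri, H, komega, lamz;
  int nCL;
  arma::vec Rmid, w; // layer midpoints and quadrature weights (sum to H)
};

// Interpolatory weights on the n equispaced midpoints of [0,1], scaled by H.
static arma::vec midpoint_weights(int n) {
  arma::mat V(n, n);
  arma::vec m(n);
  for (int p = 0; p < n; p++) {
    m(p) = 1.0 / (p + 1);
    for (int k = 0; k < n; k++)
      V(p, k) = std::pow((k + 0.5) / n, p);
  }
  return arma::solve(V, m);
}

static const int MAX_LAYERS = 63;

static Geom make_geom(double Ri, double H, double komega, double lamz, int nCL) {
  if (nCL < 1 || nCL > MAX_LAYERS || nCL % 2 == 0)
    stop("Number of wall layers must be odd and between 1 and %d.", MAX_LAYERS);
  Geom g;
  g.Ri = Ri; g.H = H; g.komega = komega; g.lamz = lamz; g.nCL = nCL;
  g.Rmid.set_size(nCL);
  for (int k = 0; k < nCL; k++) g.Rmid(k) = Ri + (k + 0.5) * H / nCL;
  g.w = midpoint_weights(nCL) * H;
  return g;
}

static Geom geom_from_pars(const List& pl) {
  return make_geom(as<double>(pl["Ri"]), as<double>(pl["H"]),
                   as<double>(pl["komega"]), as<double>(pl["lamz"]),
                   as<int>(pl["nCL"]));
}

// ---------------------------------------------------------------------------
// Signalling
// ---------------------------------------------------------------------------

static inline double logi(const Pars& p, int j, double x) {
  double y = 1.0 / (1.0 + std::exp(-p.link_slope[j] * (x - p.link_half[j])));
  return p.link_inv[j] ? 1.0 - y : y;
}

static inline double link_in(const Pars& p, int j, double P_mmHg,
                             const double* xi) {
  int c = p.link_input[j];
  return c == 0 ? P_mmHg : xi[c - 1];
}

static inline double ca_target(const Pars& p, double P_mmHg) {
  if (p.calcium_mode == 2) return 0.0;
  if (p.calcium_mode == 1)
    return p.dilt_scale /
           (1.0 + std::exp(-p.dilt_slope * (P_mmHg - p.dilt_half)));
  return logi(p, 0, link_in(p, 0, P_mmHg, nullptr));
}

// Pin the quasi-instantaneous variables xi3..xi6 to their algebraic targets.
static void sig_algebraic(const Pars& p, double P_mmHg, double* xi) {
  xi[3] = 1.0 - logi(p, 3, link_in(p, 3, P_mmHg, xi));
  xi[4] = logi(p, 4, link_in(p, 4, P_mmHg, xi));
  double c5 = logi(p, 5, link_in(p, 5, P_mmHg, xi));
  double c6 = logi(p, 6, link_in(p, 6, P_mmHg, xi));
  xi[5] = c5 / (c5 + 1.0 - c6);
  xi[6] = 1.0 - logi(p, 7, link_in(p, 7, P_mmHg, xi)) *
                logi(p, 8, link_in(p, 8, P_mmHg, xi));
}

// Two-step Adams-Bashforth on the slow variables (forward Euler at start-up),
// then the algebraic fill. xi_out/f_out may alias distinct storage only.
static void sig_step(const Pars& p, const double* xi_n, const double* f_prev,
                     bool first, double P_mmHg, double dt,
                     double* xi_out, double* f_out) {
  double f[3];
  f[0] = (ca_target(p, P_mmHg) - xi_n[0]) / p.tau_c;
  f[1] = (logi(p, 1, link_in(p, 1, P_mmHg, xi_n)) - xi_n[1]) / p.tau_c;
  f[2] = (logi(p, 2, link_in(p, 2, P_mmHg, xi_n)) - xi_n[2]) / p.tau_c;
  for (int i = 0; i < 3; i++) {
    double v = xi_n[i] + (first ? dt * f[i]
                                : dt * (1.5 * f[i] - 0.5 * f_prev[i]));
    if (v < 0) v = 0; else if (v > 1) v = 1;
    xi_out[i] = v;
    f_out[i] = f[i];
  }
  for (int i = 3; i < 7; i++) xi_out[i] = xi_n[i];
  sig_algebraic(p, P_mmHg, xi_out);
}

// ---------------------------------------------------------------------------
// Wall mechanics
// ---------------------------------------------------------------------------

static inline double cortex_stiffness(const Pars& p, double xi7) {
  double a = std::pow(xi7, p.nAC);
  return p.kACmax * a / (a + std::pow(p.KAC, p.nAC));
}

static inline double overlap(const Pars& p, double u) {
  double s = p.sf0 / p.Lm;
  double d = u - p.ufs_opt;
  return std::exp(-d * d / (2.0 * s * s));
}

// Transmural pressure integral (Eq. 13 analogue). u has nCL entries (ignored
// when active is false). Returns NaN on degenerate geometry.
static double transmural_P(const Pars& p, const Geom& g, double A,
                           const double* u, double xi5, double xi7,
                           bool active) {
  double ri2 = A / M_PI;
  double kw = g.komega, lz = g.lamz;
  double cphi = std::cos(p.phi), sphi = std::sin(p.phi);
  double kAC = active ? cortex_stiffness(p, xi7) : 0.0;
  double acc = 0.0;
  for (int k = 0; k < g.nCL; k++) {
    double R = g.Rmid(k);
    double r2 = (R * R - g.Ri * g.Ri) / (kw * lz) + ri2;
    if (r2 <= 0) return std::numeric_limits<double>::quiet_NaN();
    double r = std::sqrt(r2);
    double lt = kw * r / R, lr = R / (r * kw * lz);
    double I4 = lt * lt * cphi * cphi + lz * lz * sphi * sphi;
    double e = std::exp(p.c2 * (I4 - 1) * (I4 - 1));
    double dpt = 2 * p.c0 * lt + 2 * p.c1 * (I4 - 1) * e * lt * cphi * cphi;
    double dpr = 2 * p.c0 * lr;
    if (active) {
      double Lfo = overlap(p, u[k]);
      double ktCU = Lfo * p.Lm * xi5 * p.nXB * p.kXB / (2 * p.dm * p.NCU);
      double den = 2 * ktCU + kAC;
      double ks = den > 0 ? ktCU * kAC / den : 0.0;
      dpt += p.NCF * ks * (lt - 1.0 - 2 * p.NCU * u[k]);
    }
    acc += g.w(k) * (lt * dpt - lr * dpr) / (lt * lz * r);
  }
  return p.Pext + acc;
}

static void layer_stretch(const Geom& g, double A, double* lt) {
  double ri2 = A / M_PI;
  for (int k = 0; k < g.nCL; k++) {
    double R = g.Rmid(k);
    double r2 = (R * R - g.Ri * g.Ri) / (g.komega * g.lamz) + ri2;
    lt[k] = r2 > 0 ? g.komega * std::sqrt(r2) / R
                   : std::numeric_limits<double>::quiet_NaN();
  }
}

struct WallHist {
  const double* u_prev;   // nCL (layer-resolved) or thickness average
  const double* u_prev2;  // may be null
  const double* lt_prev;  // per layer (or average for the averaged variant)
  const double* lt_prev2; // may be null
  double dt;
  bool bdf2;
};

static inline double drate(double xnew, double xprev, double xprev2,
                           const WallHist& h) {
  return h.bdf2 ? (3 * xnew - 4 * xprev + xprev2) / (2 * h.dt)
                : (xnew - xprev) / h.dt;
}

// Residuals of the time-discretized wall system. Layer-resolved: x =
// (u_1..u_nCL, A/Aref), F has nCL+1 entries (sliding rows scaled by dt,
// pressure row in mmHg). Averaged: x = (u, A/Aref), 2 entries.
static void wall_resid(const Pars& p, const Geom& g, const WallHist& h,
                       bool averaged, double P, double xi5, double xi7,
                       double Aref, const double* x, double* F,
                       double* lt_scratch, double* u_scratch) {
  double A = x[averaged ? 1 : g.nCL] * Aref;
  if (A <= 0) { // signal infeasible iterate to the line search
    int n = averaged ? 2 : g.nCL + 1;
    for (int i = 0; i < n; i++) F[i] = 1e6;
    return;
  }
  layer_stretch(g, A, lt_scratch);
  double kAC = cortex_stiffness(p, xi7);
  double Fc_base = (p.Lm / p.dm) * xi5 * p.nXB * p.kXB * p.uPS;
  double ktCU_base = p.Lm * xi5 * p.nXB * p.kXB / (2 * p.dm * p.NCU);
  if (averaged) {
    double ltb = 0, ltb_p = h.lt_prev[0],
           ltb_p2 = h.bdf2 ? h.lt_prev2[0] : 0;
    for (int k = 0; k < g.nCL; k++) ltb += g.w(k) * lt_scratch[k];
    ltb /= g.H;
    double u = x[0];
    double Lfo = overlap(p, u);
    double ktCU = Lfo * ktCU_base;
    double den = 2 * ktCU + kAC;
    double ks = den > 0 ? ktCU * kAC / den : 0.0;
    double Fa = (ltb - 1.0 - 2 * p.NCU * u) * ks;
    double Fc = Lfo * Fc_base;
    F[0] = (drate(u, h.u_prev[0], h.bdf2 ? h.u_prev2[0] : 0, h) -
            (Fa - Fc) / p.tau_m -
            drate(ltb, ltb_p, ltb_p2, h) / (2 * p.NCU)) * h.dt;
    for (int k = 0; k < g.nCL; k++) u_scratch[k] = u;
    F[1] = (P - transmural_P(p, g, A, u_scratch, xi5, xi7,
                             p.wall_mode == 0)) / MMHG;
  } else {
    for (int k = 0; k < g.nCL; k++) {
      double u = x[k];
      double Lfo = overlap(p, u);
      double ktCU = Lfo * ktCU_base;
      double den = 2 * ktCU + kAC;
      double ks = den > 0 ? ktCU * kAC / den : 0.0;
      double Fa = (lt_scratch[k] - 1.0 - 2 * p.NCU * u) * ks;
      double Fc = Lfo * Fc_base;
      F[k] = (drate(u, h.u_prev[k], h.bdf2 ? h.u_prev2[k] : 0, h) -
              (Fa - Fc) / p.tau_m -
              drate(lt_scratch[k], h.lt_prev[k],
                    h.bdf2 ? h.lt_prev2[k] : 0, h) / (2 * p.NCU)) * h.dt;
    }
    F[g.nCL] = (P - transmural_P(p, g, A, x, xi5, xi7,
                                 p.wall_mode == 0)) / MMHG;
  }
}

// Passive wall: single unknown A solving P = P_wall(A) by scalar Newton.
static bool passive_solve(const Pars& p, const Geom& g, double P,
                          double& A, double& resid) {
  double u0[MAX_LAYERS + 1]; // content unused in the passive evaluation
  for (int k = 0; k < g.nCL; k++) u0[k] = 0.0;
  for (int it = 0; it < 60; it++) {
    double f = transmural_P(p, g, A, u0, 0, 0, false) - P;
    resid = std::fabs(f) / MMHG;
    if (resid < 1e-11) return true;
    double dA = 1e-6 * A;
    double fp = transmural_P(p, g, A + dA, u0, 0, 0, false) -
                transmural_P(p, g, A - dA, u0, 0, 0, false);
    double der = fp / (2 * dA);
    if (!std::isfinite(der) || der == 0) return false;
    double step = -f / der;
    if (step < -0.4 * A) step = -0.4 * A;
    if (step > 0.4 * A) step = 0.4 * A;
    A += step;
    if (!(A > 0)) return false;
  }
  return false;
}

struct NewtonOut { bool ok; int iters; double resid; };

// Damped Newton with finite-difference Jacobian on the wall system.
static NewtonOut wall_newton(const Pars& p, const Geom& g, const WallHist& h,
                             bool averaged, double P, double xi5, double xi7,
                             double Aref, double* x, int n) {
  arma::mat J(n, n);
  arma::vec F(n), Ft(n), step(n);
  double lts[MAX_LAYERS + 1], usc[MAX_LAYERS + 1], xt[MAX_LAYERS + 2];
  NewtonOut out{false, 0, 1e30};
  wall_resid(p, g, h, averaged, P, xi5, xi7, Aref, x, F.memptr(), lts, usc);
  double fn = arma::norm(F, "inf");
  for (int it = 0; it < 100; it++) {
    out.iters = it;
    out.resid = fn;
    if (fn < 1e-11) { out.ok = true; return out; }
    for (int c = 0; c < n; c++) {
      double eps = 1e-7 * std::max(1.0, std::fabs(x[c]));
      for (int k = 0; k < n; k++) xt[k] = x[k];
      xt[c] += eps;
      wall_resid(p, g, h, averaged, P, xi5, xi7, Aref, xt, Ft.memptr(),
                 lts, usc);
      for (int r = 0; r < n; r++) J(r, c) = (Ft(r) - F(r)) / eps;
    }
    bool solved = arma::solve(step, J, -F, arma::solve_opts::fast +
                                            arma::solve_opts::no_approx);
    if (!solved) return out;
    double lambda = 1.0;
    bool improved = false;
    for (int half = 0; half < 12; half++) {
      for (int k = 0; k < n; k++) xt[k] = x[k] + lambda * step(k);
      wall_resid(p, g, h, averaged, P, xi5, xi7, Aref, xt, Ft.memptr(),
                 lts, usc);
      double fn_t = arma::norm(Ft, "inf");
      if (std::isfinite(fn_t) && (fn_t < fn || fn_t < 1e-11)) {
        for (int k = 0; k < n; k++) x[k] = xt[k];
        F = Ft; fn = fn_t; improved = true;
        break;
      }
      lambda *= 0.5;
    }
    if (!improved) { out.resid = fn; return out; }
  }
  out.resid = fn;
  out.ok = fn < 1e-9; // accept near-tolerance stalls
  return out;
}

// Newton with retries: the quasi-static pressure balance can fold (myogenic
// snap-through), making the root nearest the previous state disappear; on
// failure, restart from a spread of area guesses (sliding reset to u_prev).
static NewtonOut wall_solve_robust(const Pars& p, const Geom& g,
                                   const WallHist& h, bool averaged, double P,
                                   double xi5, double xi7, double Aref,
                                   double* x, int n) {
  double x0[MAX_LAYERS + 2];
  for (int k = 0; k < n; k++) x0[k] = x[k];
  NewtonOut res = wall_newton(p, g, h, averaged, P, xi5, xi7, Aref, x, n);
  if (res.ok) return res;
  static const double fac[] = {0.9, 1.1, 0.8, 1.25, 0.65, 1.5, 0.5, 0.35};
  for (double f : fac) {
    for (int k = 0; k < n - 1; k++) x[k] = h.u_prev[k];
    x[n - 1] = x0[n - 1] * f;
    NewtonOut r2 = wall_newton(p, g, h, averaged, P, xi5, xi7, Aref, x, n);
    if (r2.ok) return r2;
  }
  for (int k = 0; k < n; k++) x[k] = x0[k];
  return res;
}

// Compliance dA/dP by centered difference of the frozen-state P(A) relation;
// the area perturbation corresponds to ~0.1 mmHg through the previous
// compliance (falls back to a relative perturbation at start-up).
static double compliance_fd(const Pars& p, const Geom& g, double A,
                            const double* u, double xi5, double xi7,
                            double C_prev) {
  bool active = p.wall_mode == 0;
  double dA = C_prev > 0 ? C_prev * 0.1 * MMHG : 1e-3 * A;
  if (!(dA > 0) || dA > 0.05 * A) dA = 1e-3 * A;
  double Pp = transmural_P(p, g, A + dA, u, xi5, xi7, active);
  double Pm = transmural_P(p, g, A - dA, u, xi5, xi7, active);
  double d = Pp - Pm;
  if (!std::isfinite(d) || d <= 0)
    return std::numeric_limits<double>::quiet_NaN();
  return 2 * dA / d;
}

// ---------------------------------------------------------------------------
// Network topology and flow solve
// ---------------------------------------------------------------------------

struct Topo {
  int N;                       // total nodes
  arma::ivec ei, ej;           // element node ids (0-based)
  arma::vec elen;
  arma::ivec evessel;          // element -> vessel (0-based)
  arma::ivec jp, jd1, jd2;     // junction nodes (0-based)
  int inlet;
  arma::ivec terms;            // terminal nodes (0-based)
  arma::ivec node_vessel;      // node -> vessel (0-based)
  arma::ivec mid;              // per-vessel probe node (0-based)
  std::vector<Geom> geom;      // per-vessel wall geometry
};

static Topo read_topo(const List& tl, double komega, double lamz, int nCL) {
  Topo t;
  t.N = as<int>(tl["n_nodes"]);
  IntegerVector ei = tl["elem_i"], ej = tl["elem_j"], ev = tl["elem_vessel"];
  NumericVector el = tl["elem_len"];
  int ne = ei.size();
  t.ei.set_size(ne); t.ej.set_size(ne); t.elen.set_size(ne);
  t.evessel.set_size(ne);
  for (int e = 0; e < ne; e++) {
    t.ei(e) = ei[e] - 1; t.ej(e) = ej[e] - 1;
    t.elen(e) = el[e]; t.evessel(e) = ev[e] - 1;
  }
  IntegerVector jp = tl["jun_p"], jd1 = tl["jun_d1"], jd2 = tl["jun_d2"];
  int nj = jp.size();
  t.jp.set_size(nj); t.jd1.set_size(nj); t.jd2.set_size(nj);
  for (int k = 0; k < nj; k++) {
    t.jp(k) = jp[k] - 1; t.jd1(k) = jd1[k] - 1; t.jd2(k) = jd2[k] - 1;
  }
  t.inlet = as<int>(tl["inlet_node"]) - 1;
  IntegerVector tn = tl["terminal_nodes"], nv = tl["node_vessel"],
                md = tl["mid_node"];
  t.terms.set_size(tn.size());
  for (int k = 0; k < tn.size(); k++) t.terms(k) = tn[k] - 1;
  t.node_vessel.set_size(nv.size());
  for (int k = 0; k < nv.size(); k++) t.node_vessel(k) = nv[k] - 1;
  t.mid.set_size(md.size());
  for (int k = 0; k < md.size(); k++) t.mid(k) = md[k] - 1;
  if (tl.containsElementNamed("vessel_Ri")) {
    NumericVector Ri = tl["vessel_Ri"], H = tl["vessel_H"];
    for (int v = 0; v < Ri.size(); v++)
      t.geom.push_back(make_geom(Ri[v], H[v], komega, lamz, nCL));
  }
  return t;
}

// One global flow solve. Coefficient areas/compliances (A, C) may be fixed-
// point iterates; histories and the convective term use accepted states.
static void flow_solve(const Topo& t, const Pars& p,
                       const arma::vec& A, const arma::vec& C,
                       const arma::vec& Pn, const arma::vec& Qn,
                       const arma::vec& Pn2, const arma::vec& Qn2, bool bdf2,
                       const arma::vec& Aconv, const arma::vec& Aconv2,
                       double dt, double Pin, double Pout, const arma::vec& Z,
                       arma::mat& M, arma::vec& rhs,
                       arma::vec& Pout_v, arma::vec& Qout_v) {
  int N = t.N;
  M.zeros(2 * N, 2 * N);
  rhs.zeros(2 * N);
  double beta = bdf2 ? 1.5 : 1.0;
  int row = 0;
  for (arma::uword e = 0; e < t.ei.n_elem; e++) {
    int i = t.ei(e), j = t.ej(e);
    double l2 = t.elen(e) / 2;
    if (!(A(i) > 0) || !(A(j) > 0))
      stop("Zero area in element during flow assembly.");
    double hPi = bdf2 ? (4 * Pn(i) - Pn2(i)) / (2 * dt) : Pn(i) / dt;
    double hPj = bdf2 ? (4 * Pn(j) - Pn2(j)) / (2 * dt) : Pn(j) / dt;
    double hQi = bdf2 ? (4 * Qn(i) - Qn2(i)) / (2 * dt) : Qn(i) / dt;
    double hQj = bdf2 ? (4 * Qn(j) - Qn2(j)) / (2 * dt) : Qn(j) / dt;
    // convective term, explicit: extrapolated to n+1 from the two previous
    // steps under BDF2 (plain lag at start-up)
    double s_e = (Qn(j) * Qn(j) / Aconv(j) - Qn(i) * Qn(i) / Aconv(i)) /
                 t.elen(e);
    double conv_i = p.rho / Aconv(i) * s_e, conv_j = p.rho / Aconv(j) * s_e;
    if (bdf2) {
      double s_m = (Qn2(j) * Qn2(j) / Aconv2(j) -
                    Qn2(i) * Qn2(i) / Aconv2(i)) / t.elen(e);
      conv_i = 2 * conv_i - p.rho / Aconv2(i) * s_m;
      conv_j = 2 * conv_j - p.rho / Aconv2(j) * s_m;
    }
    // mass row
    M(row, i) += l2 * C(i) * beta / dt;
    M(row, j) += l2 * C(j) * beta / dt;
    M(row, N + i) += -1.0;
    M(row, N + j) += 1.0;
    rhs(row) = l2 * (C(i) * hPi + C(j) * hPj);
    row++;
    // momentum row (friction implicit, convection explicit)
    M(row, N + i) += l2 * (p.rho / A(i)) * beta / dt +
                     l2 * 8 * M_PI * p.mu / (A(i) * A(i));
    M(row, N + j) += l2 * (p.rho / A(j)) * beta / dt +
                     l2 * 8 * M_PI * p.mu / (A(j) * A(j));
    M(row, i) += -1.0;
    M(row, j) += 1.0;
    rhs(row) = l2 * (p.rho / A(i) * hQi + p.rho / A(j) * hQj) -
               l2 * (conv_i + conv_j);
    row++;
  }
  for (arma::uword k = 0; k < t.jp.n_elem; k++) {
    M(row, t.jp(k)) = 1; M(row, t.jd1(k)) = -1; row++;
    M(row, t.jp(k)) = 1; M(row, t.jd2(k)) = -1; row++;
    M(row, N + t.jp(k)) = 1; M(row, N + t.jd1(k)) = -1;
    M(row, N + t.jd2(k)) = -1; row++;
  }
  M(row, t.inlet) = 1; rhs(row) = Pin; row++;
  for (arma::uword k = 0; k < t.terms.n_elem; k++) {
    M(row, t.terms(k)) = 1;
    M(row, N + t.terms(k)) = -Z(k);
    rhs(row) = Pout;
    row++;
  }
  if (row != 2 * N) stop("Flow system is not square: unconstrained nodes.");
  // equilibrate rows then columns: pressure and flow columns differ by many
  // orders of magnitude in CGS units
  arma::vec rscale = arma::max(arma::abs(M), 1);
  rscale.replace(0.0, 1.0);
  M.each_col() /= rscale;
  arma::vec rhs_s = rhs / rscale;
  arma::rowvec cscale = arma::max(arma::abs(M), 0);
  cscale.replace(0.0, 1.0);
  M.each_row() /= cscale;
  arma::vec sol;
  if (!arma::solve(sol, M, rhs_s, arma::solve_opts::fast +
                                    arma::solve_opts::no_approx))
    stop("Singular global flow matrix.");
  sol /= cscale.t();
  Pout_v = sol.subvec(0, N - 1);
  Qout_v = sol.subvec(N, 2 * N - 1);
}

// ---------------------------------------------------------------------------
// Exported elementary operations (cross-checked against the R reference)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_transmural_pressure(List pars, double A, NumericVector u,
                               double xi5, double xi7, bool active = true) {
  Pars p = read_pars(pars);
  Geom g = geom_from_pars(pars);
  if ((int)u.size() != g.nCL) stop("u must have one entry per layer");
  return transmural_P(p, g, A, u.begin(), xi5, xi7, active);
}

// [[Rcpp::export]]
List cpp_wall_step(List pars, NumericVector u_prev, double A_prev,
                   NumericVector u_prev2, double A_prev2,
                   double P_new, double xi5, double xi7, double dt,
                   double C_prev, bool averaged) {
  Pars p = read_pars(pars);
  Geom g = geom_from_pars(pars);
  int nCL = g.nCL;
  bool bdf2 = A_prev2 > 0 && u_prev2.size() > 0;
  double Aref = M_PI * g.Ri * g.Ri / (g.komega * g.komega);
  std::vector<double> ltp(nCL), ltp2(nCL), up(nCL), up2(nCL);
  layer_stretch(g, A_prev, ltp.data());
  if (bdf2) layer_stretch(g, A_prev2, ltp2.data());
  double x[MAX_LAYERS + 2];
  int n;
  double wsum = 0;
  if (averaged) {
    double ub = 0, ub2 = 0, ltb = 0, ltb2 = 0;
    for (int k = 0; k < nCL; k++) {
      wsum += g.w(k);
      ub += g.w(k) * u_prev[k];
      ltb += g.w(k) * ltp[k];
      if (bdf2) { ub2 += g.w(k) * u_prev2[k]; ltb2 += g.w(k) * ltp2[k]; }
    }
    up[0] = ub / wsum; ltp[0] = ltb / wsum;
    if (bdf2) { up2[0] = ub2 / wsum; ltp2[0] = ltb2 / wsum; }
    x[0] = up[0]; x[1] = A_prev / Aref;
    n = 2;
  } else {
    for (int k = 0; k < nCL; k++) {
      up[k] = u_prev[k];
      if (bdf2) up2[k] = u_prev2[k];
      x[k] = u_prev[k];
    }
    x[nCL] = A_prev / Aref;
    n = nCL + 1;
  }
  WallHist h{up.data(), bdf2 ? up2.data() : nullptr, ltp.data(),
             bdf2 ? ltp2.data() : nullptr, dt, bdf2};
  NewtonOut res;
  double A_new;
  NumericVector u_new(nCL);
  if (p.wall_mode == 1) { // passive tube: pressure balance only
    A_new = A_prev;
    double rn;
    bool ok = passive_solve(p, g, P_new, A_new, rn);
    res.ok = ok; res.resid = rn; res.iters = 0;
    for (int k = 0; k < nCL; k++) u_new[k] = u_prev[k];
  } else {
    res = wall_solve_robust(p, g, h, averaged, P_new, xi5, xi7, Aref, x, n);
    A_new = x[averaged ? 1 : nCL] * Aref;
    for (int k = 0; k < nCL; k++) u_new[k] = averaged ? x[0] : x[k];
  }
  double C = compliance_fd(p, g, A_new, u_new.begin(), xi5, xi7, C_prev);
  return List::create(_["u"] = u_new, _["A"] = A_new, _["C_A"] = C,
                      _["converged"] = res.ok, _["resid_norm"] = res.resid,
                      _["n_iter"] = res.iters);
}

// [[Rcpp::export]]
List cpp_flow_step(List topo, List pars, List state, double dt,
                   double Pin, double Pout, NumericVector Z,
                   double komega = 1.0, double lamz = 1.0, int nCL = 5) {
  Pars p = read_pars(pars);
  Topo t = read_topo(topo, komega, lamz, nCL);
  arma::vec A = as<arma::vec>(state["A"]), C = as<arma::vec>(state["C_A"]);
  arma::vec Pn = as<arma::vec>(state["P"]), Qn = as<arma::vec>(state["Q"]);
  bool bdf2 = state.containsElementNamed("P2") &&
              !Rf_isNull(state["P2"]);
  arma::vec Pn2, Qn2;
  if (bdf2) {
    Pn2 = as<arma::vec>(state["P2"]);
    Qn2 = as<arma::vec>(state["Q2"]);
  } else {
    Pn2.zeros(t.N); Qn2.zeros(t.N);
  }
  arma::vec Aconv = state.containsElementNamed("A_prev") &&
                    !Rf_isNull(state["A_prev"])
                        ? as<arma::vec>(state["A_prev"]) : A;
  arma::vec Aconv2 = state.containsElementNamed("A_prev2") &&
                     !Rf_isNull(state["A_prev2"])
                         ? as<arma::vec>(state["A_prev2"]) : Aconv;
  arma::vec Zv(t.terms.n_elem);
  if (Z.size() == 1) Zv.fill(Z[0]);
  else for (arma::uword k = 0; k < t.terms.n_elem; k++) Zv(k) = Z[k];
  arma::mat M; arma::vec rhs, Pv, Qv;
  flow_solve(t, p, A, C, Pn, Qn, Pn2, Qn2, bdf2, Aconv, Aconv2, dt, Pin,
             Pout, Zv, M, rhs, Pv, Qv);
  return List::create(_["P"] = Pv, _["Q"] = Qv);
}

// ---------------------------------------------------------------------------
// Single-vessel (pressure-clamp) protocol
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_single_vessel(List pars, NumericVector Pvals, double dt,
                       bool averaged = false) {
  Pars p = read_pars(pars);
  Geom g = geom_from_pars(pars);
  int nCL = g.nCL;
  int nsteps = Pvals.size() - 1;
  double Aref = M_PI * g.Ri * g.Ri / (g.komega * g.komega);
  double Ro = g.Ri + g.H;

  std::vector<double> u(nCL, -2e-2), u_prev(nCL, -2e-2);
  double A = Aref, A_prev = Aref;
  double xi[7] = {0, 0, 0, 0, 0, 0, 0};
  double fs[3] = {0, 0, 0};
  double C = compliance_fd(p, g, A, u.data(), xi[5], 1 - xi[6], -1);

  NumericMatrix xi_rec(nsteps + 1, 7), u_rec(nsteps + 1, nCL);
  NumericVector A_rec(nsteps + 1), di(nsteps + 1), do_(nsteps + 1),
                ufs(nsteps + 1), C_rec(nsteps + 1);
  auto record = [&](int n) {
    double ri = std::sqrt(A / M_PI);
    di[n] = 2 * ri;
    do_[n] = 2 * std::sqrt((Ro * Ro - g.Ri * g.Ri) / (g.komega * g.lamz) +
                           ri * ri);
    A_rec[n] = A; C_rec[n] = C;
    double ub = 0, ws = 0;
    for (int k = 0; k < nCL; k++) { ub += g.w(k) * u[k]; ws += g.w(k); }
    ufs[n] = ub / ws;
    for (int k = 0; k < nCL; k++) u_rec(n, k) = u[k];
    for (int k = 0; k < 7; k++) xi_rec(n, k) = xi[k];
  };
  record(0);

  for (int n = 0; n < nsteps; n++) {
    bool first = (n == 0);
    double P = Pvals[n + 1];
    double xin[7], fn[3];
    sig_step(p, xi, fs, first, P / MMHG, dt, xin, fn);
    std::vector<double> ltp(nCL), ltp2(nCL), up(nCL), up2(nCL);
    layer_stretch(g, A, ltp.data());
    if (!first) layer_stretch(g, A_prev, ltp2.data());
    double x[MAX_LAYERS + 2];
    int nun;
    if (averaged) {
      double ub = 0, ub2 = 0, ltb = 0, ltb2 = 0, ws = 0;
      for (int k = 0; k < nCL; k++) {
        ws += g.w(k); ub += g.w(k) * u[k]; ltb += g.w(k) * ltp[k];
        if (!first) { ub2 += g.w(k) * u_prev[k]; ltb2 += g.w(k) * ltp2[k]; }
      }
      up[0] = ub / ws; ltp[0] = ltb / ws;
      if (!first) { up2[0] = ub2 / ws; ltp2[0] = ltb2 / ws; }
      x[0] = up[0]; x[1] = A / Aref; nun = 2;
    } else {
      for (int k = 0; k < nCL; k++) {
        up[k] = u[k];
        if (!first) up2[k] = u_prev[k];
        x[k] = u[k];
      }
      x[nCL] = A / Aref; nun = nCL + 1;
    }
    WallHist h{up.data(), first ? nullptr : up2.data(), ltp.data(),
               first ? nullptr : ltp2.data(), dt, !first};
    double A_new;
    std::vector<double> u_new(nCL);
    if (p.wall_mode == 1) {
      A_new = A;
      double rn;
      if (!passive_solve(p, g, P, A_new, rn))
        stop("Passive wall solve failed at t = %g s.", (n + 1) * dt);
      u_new = u;
    } else {
      NewtonOut res = wall_solve_robust(p, g, h, averaged, P, xin[5], 1 - xin[6],
                                  Aref, x, nun);
      if (!res.ok)
        stop("Wall solve failed at t = %g s (residual %g).",
             (n + 1) * dt, res.resid);
      A_new = x[averaged ? 1 : nCL] * Aref;
      for (int k = 0; k < nCL; k++) u_new[k] = averaged ? x[0] : x[k];
    }
    C = compliance_fd(p, g, A_new, u_new.data(), xin[5], 1 - xin[6], C);
    u_prev = u; u = u_new;
    A_prev = A; A = A_new;
    for (int k = 0; k < 7; k++) xi[k] = xin[k];
    for (int k = 0; k < 3; k++) fs[k] = fn[k];
    record(n + 1);
  }
  return List::create(_["A"] = A_rec, _["di"] = di, _["do"] = do_,
                      _["ufs"] = ufs, _["u"] = u_rec, _["xi"] = xi_rec,
                      _["C_A"] = C_rec);
}

// ---------------------------------------------------------------------------
// Coupled network simulation
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate(List topo, List pars, NumericVector inlet, List conf,
                  Nullable<List> init = R_NilValue) {
  Pars p = read_pars(pars);
  double dt = conf["dt"];
  int n_steps = as<int>(conf["n_steps"]);
  int coupling = as<int>(conf["coupling"]); // 0 weak, 1 strong
  double eps = conf["eps"];
  int max_iters = as<int>(conf["max_iters"]);
  bool averaged = as<bool>(conf["averaged"]);
  int record_every = as<int>(conf["record_every"]);
  double Pout = conf["Pout"];
  int z_mode = as<int>(conf["z_mode"]); // 0 none, 1 characteristic, 2 fixed
  double z_value = conf["z_value"];
  double komega = conf["komega"], lamz = conf["lamz"];
  int nCL = as<int>(conf["nCL"]);
  Topo t = read_topo(topo, komega, lamz, nCL);
  int N = t.N, nv = t.mid.n_elem;
  bool rigid = p.wall_mode == 2;
  bool passive = p.wall_mode == 1;
  if ((int)inlet.size() != n_steps + 1)
    stop("Inlet signal must supply n_steps + 1 samples.");

  arma::vec P(N), Q(N), Pprev(N), Qprev(N), A(N), Aprev(N), C(N);
  arma::mat u(nCL, N), uprev(nCL, N), xi(7, N), fs(3, N);
  bool has_hist = false;
  arma::vec Z(t.terms.n_elem, arma::fill::zeros);

  auto Aref_of = [&](int node) {
    const Geom& g = t.geom[t.node_vessel(node)];
    return M_PI * g.Ri * g.Ri / (g.komega * g.komega);
  };

  if (init.isNotNull()) {
    List st(init);
    P = as<arma::vec>(st["P"]); Q = as<arma::vec>(st["Q"]);
    A = as<arma::vec>(st["A"]); C = as<arma::vec>(st["C_A"]);
    u = as<arma::mat>(st["u"]); xi = as<arma::mat>(st["xi"]);
    fs = as<arma::mat>(st["f_sig"]);
    has_hist = as<bool>(st["has_hist"]);
    if (has_hist) {
      Pprev = as<arma::vec>(st["P_prev"]); Qprev = as<arma::vec>(st["Q_prev"]);
      Aprev = as<arma::vec>(st["A_prev"]); uprev = as<arma::mat>(st["u_prev"]);
    } else {
      Pprev = P; Qprev = Q; Aprev = A; uprev = u;
    }
    Z = as<arma::vec>(st["Z"]);
  } else {
    P.fill(inlet[0]); Q.zeros();
    u.fill(-2e-2); xi.zeros(); fs.zeros();
    for (int i = 0; i < N; i++) A(i) = Aref_of(i);
    for (int i = 0; i < N; i++) {
      const Geom& g = t.geom[t.node_vessel(i)];
      C(i) = rigid ? 0.0
                   : compliance_fd(p, g, A(i), u.colptr(i), xi(5, i),
                                   1 - xi(6, i), -1);
      if (!rigid && !std::isfinite(C(i)))
        stop("Non-finite initial compliance at node %d.", i + 1);
    }
    Pprev = P; Qprev = Q; Aprev = A; uprev = u;
    if (z_mode == 1) {
      for (arma::uword k = 0; k < t.terms.n_elem; k++) {
        int nd = t.terms(k);
        if (rigid) stop("Characteristic impedance needs compliant walls.");
        double c_pw = std::sqrt(A(nd) / (p.rho * C(nd)));
        Z(k) = p.rho * c_pw / A(nd);
      }
    } else if (z_mode == 2) {
      Z.fill(z_value);
    }
  }

  int n_rec = n_steps / record_every + 1;
  NumericVector t_rec(n_rec);
  NumericMatrix Pr(n_rec, nv), Qr(n_rec, nv), Ar(n_rec, nv),
                dir(n_rec, nv), dor(n_rec, nv), ur(n_rec, nv);
  IntegerVector iters(std::max(n_steps, 1));
  NumericVector rms_fin(std::max(n_steps, 1));
  int rec = 0;
  auto record = [&](double time) {
    t_rec[rec] = time;
    for (int v = 0; v < nv; v++) {
      int nd = t.mid(v);
      const Geom& g = t.geom[v];
      double ri = std::sqrt(A(nd) / M_PI);
      double Ro = g.Ri + g.H;
      Pr(rec, v) = P(nd); Qr(rec, v) = Q(nd); Ar(rec, v) = A(nd);
      dir(rec, v) = 2 * ri;
      dor(rec, v) = 2 * std::sqrt((Ro * Ro - g.Ri * g.Ri) /
                                  (g.komega * g.lamz) + ri * ri);
      double ub = 0, ws = 0;
      for (int k = 0; k < nCL; k++) { ub += g.w(k) * u(k, nd); ws += g.w(k); }
      ur(rec, v) = ub / ws;
    }
    rec++;
  };
  record(0.0);

  double max_jun_abs = 0.0, max_absQ = 1e-300;
  double wct0 = (double)clock() / CLOCKS_PER_SEC;

  arma::mat Mwork; arma::vec rhswork;
  arma::vec Pit(N), Qit(N), Anew(N), Cnew(N);
  arma::mat unew(nCL, N), xin(7, N), fn(3, N);

  for (int n = 0; n < n_steps; n++) {
    double Pin = inlet[n + 1];
    bool bdf2 = has_hist;
    arma::vec A_it = A, C_it = C;
    double r = 0, r_prev = std::numeric_limits<double>::infinity();
    int grow = 0, it_count = 0;
    // per-node loop-invariant histories
    for (int iter = 1; iter <= max_iters; iter++) {
      it_count = iter;
      flow_solve(t, p, A_it, C_it, P, Q, Pprev, Qprev, bdf2, A, Aprev, dt,
                 Pin, Pout, Z, Mwork, rhswork, Pit, Qit);
      if (rigid) {
        Anew = A; Cnew = C; unew = u; xin = xi; fn = fs;
        r = 0;
        break;
      }
      for (int nd = 0; nd < N; nd++) {
        const Geom& g = t.geom[t.node_vessel(nd)];
        double xtmp[7], ftmp[3];
        double xi_col[7];
        for (int k = 0; k < 7; k++) xi_col[k] = xi(k, nd);
        double fs_col[3] = {fs(0, nd), fs(1, nd), fs(2, nd)};
        sig_step(p, xi_col, fs_col, !bdf2 && !has_hist, Pit(nd) / MMHG, dt,
                 xtmp, ftmp);
        double xi5 = xtmp[5], xi7 = 1 - xtmp[6];
        double Aref = M_PI * g.Ri * g.Ri / (g.komega * g.komega);
        int nun = averaged ? 2 : nCL + 1;
        std::vector<double> ltp(nCL), ltp2(nCL), up(nCL), up2(nCL);
        layer_stretch(g, A(nd), ltp.data());
        if (bdf2) layer_stretch(g, Aprev(nd), ltp2.data());
        double x[MAX_LAYERS + 2];
        if (averaged) {
          double ub = 0, ub2 = 0, ltb = 0, ltb2 = 0, ws = 0;
          for (int k = 0; k < nCL; k++) {
            ws += g.w(k); ub += g.w(k) * u(k, nd); ltb += g.w(k) * ltp[k];
            if (bdf2) {
              ub2 += g.w(k) * uprev(k, nd); ltb2 += g.w(k) * ltp2[k];
            }
          }
          up[0] = ub / ws; ltp[0] = ltb / ws;
          if (bdf2) { up2[0] = ub2 / ws; ltp2[0] = ltb2 / ws; }
          x[0] = up[0];
          x[1] = (iter == 1 ? A(nd) : Anew(nd)) / Aref;
        } else {
          for (int k = 0; k < nCL; k++) {
            up[k] = u(k, nd);
            if (bdf2) up2[k] = uprev(k, nd);
            x[k] = iter == 1 ? u(k, nd) : unew(k, nd);
          }
          x[nCL] = (iter == 1 ? A(nd) : Anew(nd)) / Aref;
        }
        WallHist h{up.data(), bdf2 ? up2.data() : nullptr, ltp.data(),
                   bdf2 ? ltp2.data() : nullptr, dt, bdf2};
        double A_new;
        if (passive) {
          A_new = iter == 1 ? A(nd) : Anew(nd);
          double rn;
          if (!passive_solve(p, g, Pit(nd), A_new, rn))
            stop("Passive wall solve failed at t = %g s, node %d.",
                 (n + 1) * dt, nd + 1);
          for (int k = 0; k < nCL; k++) unew(k, nd) = u(k, nd);
        } else {
          NewtonOut res = wall_solve_robust(p, g, h, averaged, Pit(nd), xi5, xi7,
                                      Aref, x, nun);
          if (!res.ok)
            stop("Wall solve failed at t = %g s, node %d (residual %g).",
                 (n + 1) * dt, nd + 1, res.resid);
          A_new = x[averaged ? 1 : nCL] * Aref;
          for (int k = 0; k < nCL; k++)
            unew(k, nd) = averaged ? x[0] : x[k];
        }
        Anew(nd) = A_new;
        Cnew(nd) = compliance_fd(p, g, A_new, unew.colptr(nd), xi5, xi7,
                                 C(nd));
        if (!std::isfinite(Cnew(nd)))
          stop("Non-finite compliance at t = %g s, node %d.",
               (n + 1) * dt, nd + 1);
        for (int k = 0; k < 7; k++) xin(k, nd) = xtmp[k];
        for (int k = 0; k < 3; k++) fn(k, nd) = ftmp[k];
      }
      // area RMSRE between successive iterates across the network
      double acc = 0;
      for (int nd = 0; nd < N; nd++) {
        double d = (Anew(nd) - A_it(nd)) / A_it(nd);
        acc += d * d;
      }
      r = std::sqrt(acc / N);
      if (!std::isfinite(r))
        stop("Non-finite state at t = %g s: simulation unstable.",
             (n + 1) * dt);
      if (coupling == 0 || r < eps) break;
      if (r >= r_prev) { if (++grow >= 10)
        stop("Fixed-point iteration diverging at t = %g s (RMSRE %g).",
             (n + 1) * dt, r);
      } else grow = 0;
      r_prev = r;
      if (iter == max_iters)
        stop("Coupling failed to converge in %d iterations at t = %g s "
             "(last RMSRE %g).", max_iters, (n + 1) * dt, r);
      A_it = Anew; C_it = Cnew;
    }
    iters[n] = it_count;
    rms_fin[n] = r;
    // accept the step
    Pprev = P; Qprev = Q; P = Pit; Q = Qit;
    Aprev = A; A = Anew; C = Cnew;
    uprev = u; u = unew; xi = xin; fs = fn;
    has_hist = true;
    if (!P.is_finite() || !Q.is_finite())
      stop("Non-finite pressure/flow at t = %g s.", (n + 1) * dt);
    for (arma::uword k = 0; k < t.jp.n_elem; k++) {
      double res = std::fabs(Q(t.jp(k)) - Q(t.jd1(k)) - Q(t.jd2(k)));
      if (res > max_jun_abs) max_jun_abs = res;
    }
    double mq = arma::abs(Q).max();
    if (mq > max_absQ) max_absQ = mq;
    if ((n + 1) % record_every == 0) record((n + 1) * dt);
  }
  double wct = (double)clock() / CLOCKS_PER_SEC - wct0;

  List final_state = List::create(
      _["P"] = P, _["Q"] = Q, _["A"] = A, _["C_A"] = C, _["u"] = u,
      _["xi"] = xi, _["f_sig"] = fs, _["P_prev"] = Pprev,
      _["Q_prev"] = Qprev, _["A_prev"] = Aprev, _["u_prev"] = uprev,
      _["has_hist"] = has_hist, _["Z"] = Z);
  if (n_steps == 0) {
    iters = IntegerVector(0);
    rms_fin = NumericVector(0);
  }
  return List::create(
      _["t_rec"] = t_rec, _["P"] = Pr, _["Q"] = Qr, _["A"] = Ar,
      _["di"] = dir, _["do"] = dor, _["ufs"] = ur, _["iters"] = iters,
      _["rmsre_final"] = rms_fin, _["max_jun_abs"] = max_jun_abs,
      _["max_jun_rel"] = max_jun_abs / max_absQ, _["Z"] = Z,
      _["wct"] = wct, _["final_state"] = final_state);
}
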