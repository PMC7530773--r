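// Compiled core: fixed-step RK4 method-of-steps integrator for multi-layer
// networks with per-layer transmission delays, the neuron/synapse model
// library (right-hand sides and analytic Jacobians), and the transverse
// variational integrator used for Lyapunov-exponent estimation.
//
// Conventions:
//  - adjacency A[i][j] = weight of link j -> i (row = postsynaptic node);
//  - node states are padded to a common dimension n; components beyond a
//    model's native dimension are masked to exact zero;
//  - delays must be non-negative integer multiples of the step (the R side
//    adjusts the step); zero delays are evaluated at the current RK4 stage.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// model ids: 1 = swim (conductance-based, n=7), 2 = hindmarsh-rose (n=3),
//            3 = linear (n=1)
// kind ids:  1 = dynamical inhibitory chemical, 2 = dynamical excitatory
//            chemical, 3 = electrical / diffusive (V_j - V_i),
//            4 = fast threshold modulation, 5 = direct (V_j)
// ---------------------------------------------------------------------------

static inline int model_dim_c(int id) {
  switch (id) {
  case 1: return 7;
  case 2: return 3;
  case 3: return 1;
  default: stop("unknown model id");
  }
  return 0;
}

// ---- swim neuron (Plant-type bursting model) ------------------------------
// params: 0 C, 1 gNa, 2 VNa, 3 gK, 4 VK, 5 gCa, 6 VCa_rev, 7 gKCa, 8 gL,
//         9 VL, 10 rho, 11 Kc, 12 VCa_drive, 13 tau_chi, 14 tau_s, 15 VT,
//         16 Vs_syn, 17 s_clamp
struct SwimGates {
  double minf, dminf;       // m_inf(V), d m_inf / dV
  double hinf, tauh, dhinf, dtauh;
  double ninf, taun, dninf, dtaun;
};

static void swim_gates(double V, SwimGates &g) {
  const double c = 127.0 / 105.0;        // dVs/dV
  const double Vs = (127.0 * V + 8265.0) / 105.0;

  // alpha_m = 0.1 u / (e^{u/10} - 1), u = 50 - Vs
  {
    double u = 50.0 - Vs, z = u / 10.0;
    double g1 = std::expm1(z);
    double am, dam; // d/du
    if (std::fabs(z) < 1e-7) { am = 1.0 - z / 2.0; dam = -0.05; }
    else {
      am = 0.1 * u / g1;
      dam = 0.1 * (g1 - z * std::exp(z)) / (g1 * g1);
    }
    double bm = 4.0 * std::exp((25.0 - Vs) / 18.0);
    double dbm_dV = bm * (-1.0 / 18.0) * c;
    double dam_dV = dam * (-c);
    double s = am + bm;
    g.minf = am / s;
    g.dminf = (dam_dV * bm - am * dbm_dV) / (s * s);
  }
  // h gates
  {
    double ah = 0.07 * std::exp((25.0 - Vs) / 20.0);
    double dah_dV = ah * (-1.0 / 20.0) * c;
    double w = (55.0 - Vs) / 10.0;
    double ew = std::exp(w);
    double bh = 1.0 / (ew + 1.0);
    // dbh/dV = e^w/(e^w+1)^2 * (c/10)
    double dbh_dV = ew / ((ew + 1.0) * (ew + 1.0)) * (c / 10.0);
    double s = ah + bh, ds = dah_dV + dbh_dV;
    g.hinf = ah / s;
    g.dhinf = (dah_dV * s - ah * ds) / (s * s);
    g.tauh = 12.5 / s;
    g.dtauh = -12.5 * ds / (s * s);
  }
  // n gates: alpha_n = 0.01 u / (e^{u/10} - 1), u = 55 - Vs  (the canonical
  // 0.01 rate scale of the underlying Hodgkin-Huxley kinetics; without it
  // the K gate saturates at rest and the neuron cannot spike)
  {
    double u = 55.0 - Vs, z = u / 10.0;
    double g1 = std::expm1(z);
    double an, dan; // d/du
    if (std::fabs(z) < 1e-7) { an = 0.1 * (1.0 - z / 2.0); dan = -0.005; }
    else {
      an = 0.01 * u / g1;
      dan = 0.01 * (g1 - z * std::exp(z)) / (g1 * g1);
    }
    double dan_dV = dan * (-c);
    double bn = 0.125 * std::exp((45.0 - Vs) / 80.0);
    double dbn_dV = bn * (-1.0 / 80.0) * c;
    double s = an + bn, ds = dan_dV + dbn_dV;
    g.ninf = an / s;
    g.dninf = (dan_dV * s - an * ds) / (s * s);
    g.taun = 12.5 / s;
    g.dtaun = -12.5 * ds / (s * s);
  }
}

// chi gate: chi_inf = 1/(1 + e^{-k (V - V0)}) evaluated in V directly
static inline void swim_chi(double V, double k, double V0,
                            double &chinf, double &dchinf) {
  double e = std::exp(-k * (V - V0));
  double d = 1.0 + e;
  chinf = 1.0 / d;
  dchinf = k * e / (d * d);
}

// synaptic gate steady state with clamp, and derivative
static inline void swim_sinf(double V, double VT, double Vss, double clamp,
                             double &sinf, double &dsinf) {
  if (V > VT) {
    double th = std::tanh((V - VT) / Vss);
    sinf = th; dsinf = (1.0 - th * th) / Vss;
    double top = 1.0 - clamp;
    if (sinf > top) { sinf = top; dsinf = 0.0; }
  } else { sinf = 0.0; dsinf = 0.0; }
}

static void swim_rhs(const double *p, const double *x, double *dx) {
  const double C = p[0], gNa = p[1], VNa = p[2], gK = p[3], VK = p[4],
    gCa = p[5], VCaR = p[6], gKCa = p[7], gL = p[8], VL = p[9], rho = p[10],
    Kc = p[11], VCaD = p[12], tch = p[13], ts = p[14], VT = p[15],
    Vss = p[16], clamp = p[17], chik = p[18], chiV0 = p[19];
  const double V = x[0], h = x[1], n = x[2], chi = x[3], Ca = x[4];
  SwimGates g; swim_gates(V, g);
  double chinf, dchinf; swim_chi(V, chik, chiV0, chinf, dchinf);
  double INa = gNa * g.minf * g.minf * g.minf * h * (V - VNa);
  double IK  = gK * n * n * n * n * (V - VK);
  double ICa = gCa * chi * (V - VCaR);
  double IKCa = gKCa * Ca / (0.5 + Ca) * (V - VK);
  double Il = gL * (V - VL);
  dx[0] = (-INa - IK - ICa - IKCa - Il) / C;
  dx[1] = (g.hinf - h) / g.tauh;
  dx[2] = (g.ninf - n) / g.taun;
  dx[3] = (chinf - chi) / tch;
  dx[4] = rho * (Kc * chi * (VCaD - V) - Ca);
  double sinf, dsinf; swim_sinf(V, VT, Vss, clamp, sinf, dsinf);
  dx[5] = (sinf - x[5]) / (ts * (1.0 - sinf));
  dx[6] = (sinf - x[6]) / (ts * (1.0 - sinf));
}

static void swim_jac(const double *p, const double *x, double *J, int ld) {
  // J is ld x ld column-major; fills the native 7x7 corner
  const double C = p[0], gNa = p[1], VNa = p[2], gK = p[3], VK = p[4],
    gCa = p[5], VCaR = p[6], gKCa = p[7], gL = p[8], rho = p[10],
    Kc = p[11], VCaD = p[12], tch = p[13], ts = p[14], VT = p[15],
    Vss = p[16], clamp = p[17], chik = p[18], chiV0 = p[19];
  const double V = x[0], h = x[1], n = x[2], chi = x[3], Ca = x[4];
  SwimGates g; swim_gates(V, g);
  double chinf, dchinf; swim_chi(V, chik, chiV0, chinf, dchinf);
  for (int j = 0; j < 7; ++j)
    for (int i = 0; i < 7; ++i) J[i + ld * j] = 0.0;
  double m3 = g.minf * g.minf * g.minf;
  // dV/d.
  double dINa_dV = gNa * (3.0 * g.minf * g.minf * g.dminf * h * (V - VNa) + m3 * h);
  double dIK_dV = gK * n * n * n * n;
  double dICa_dV = gCa * chi;
  double dIKCa_dV = gKCa * Ca / (0.5 + Ca);
  double dIl_dV = gL;
  J[0 + ld * 0] = -(dINa_dV + dIK_dV + dICa_dV + dIKCa_dV + dIl_dV) / C;
  J[0 + ld * 1] = -(gNa * m3 * (V - VNa)) / C;                      // d/dh
  J[0 + ld * 2] = -(4.0 * gK * n * n * n * (V - VK)) / C;           // d/dn
  J[0 + ld * 3] = -(gCa * (V - VCaR)) / C;                          // d/dchi
  J[0 + ld * 4] = -(gKCa * 0.5 / ((0.5 + Ca) * (0.5 + Ca)) * (V - VK)) / C;
  // gating rows: d/dt y = (yinf - y)/tau
  J[1 + ld * 0] = (g.dhinf * g.tauh - (g.hinf - h) * g.dtauh) / (g.tauh * g.tauh);
  J[1 + ld * 1] = -1.0 / g.tauh;
  J[2 + ld * 0] = (g.dninf * g.taun - (g.ninf - n) * g.dtaun) / (g.taun * g.taun);
  J[2 + ld * 2] = -1.0 / g.taun;
  J[3 + ld * 0] = dchinf / tch;
  J[3 + ld * 3] = -1.0 / tch;
  J[4 + ld * 0] = -rho * Kc * chi;
  J[4 + ld * 3] = rho * Kc * (VCaD - V);
  J[4 + ld * 4] = -rho;
  double sinf, dsinf; swim_sinf(V, VT, Vss, clamp, sinf, dsinf);
  double om = 1.0 - sinf;
  for (int r = 5; r <= 6; ++r) {
    J[r + ld * 0] = dsinf * (1.0 - x[r]) / (ts * om * om);
    J[r + ld * r] = -1.0 / (ts * om);
  }
}

// ---- Hindmarsh-Rose -------------------------------------------------------
// params: 0 b, 1 mu, 2 s, 3 xrest, 4 I
static void hr_rhs(const double *p, const double *x, double *dx) {
  const double b = p[0], mu = p[1], s = p[2], xr = p[3], I = p[4];
  const double V = x[0], y = x[1], z = x[2];
  dx[0] = y - V * V * V + b * V * V - z + I;
  dx[1] = 1.0 - 5.0 * V * V - y;
  dx[2] = mu * (s * (V - xr) - z);
}

static void hr_jac(const double *p, const double *x, double *J, int ld) {
  const double b = p[0], mu = p[1], s = p[2];
  const double V = x[0];
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) J[i + ld * j] = 0.0;
  J[0 + ld * 0] = -3.0 * V * V + 2.0 * b * V;
  J[0 + ld * 1] = 1.0;
  J[0 + ld * 2] = -1.0;
  J[1 + ld * 0] = -10.0 * V;
  J[1 + ld * 1] = -1.0;
  J[2 + ld * 0] = mu * s;
  J[2 + ld * 2] = -mu;
}

// ---- linear ---------------------------------------------------------------
static void lin_rhs(const double *p, const double *x, double *dx) {
  dx[0] = p[0] * x[0];
}
static void lin_jac(const double *p, const double *, double *J, int ld) {
  J[0] = p[0]; (void)ld;
}

static void model_rhs_c(int id, const double *p, const double *x, double *dx) {
  switch (id) {
  case 1: swim_rhs(p, x, dx); break;
  case 2: hr_rhs(p, x, dx); break;
  case 3: lin_rhs(p, x, dx); break;
  default: stop("unknown model id");
  }
}
static void model_jac_c(int id, const double *p, const double *x, double *J, int ld) {
  switch (id) {
  case 1: swim_jac(p, x, J, ld); break;
  case 2: hr_jac(p, x, J, ld); break;
  case 3: lin_jac(p, x, J, ld); break;
  default: stop("unknown model id");
  }
}

// ---- synapse activations --------------------------------------------------
// xi: postsynaptic state (current time), xj: presynaptic state (delayed)
static inline double ftm_gamma(double Vj, double nu, double theta) {
  double e = nu * (Vj - theta);
  if (e > 50.0) return 0.0;
  if (e < -50.0) return 1.0;
  return 1.0 / (1.0 + std::exp(e));
}

static double activation_c(int kind, const double *kp, const double *xi,
                           const double *xj) {
  switch (kind) {
  case 1: return (kp[0] - xi[0]) * xj[5];
  case 2: return (kp[0] - xi[0]) * xj[6];
  case 3: return xj[0] - xi[0];
  case 4: return (kp[0] - xi[0]) * ftm_gamma(xj[0], kp[1], kp[2]);
  case 5: return xj[0];
  default: stop("unknown coupling kind");
  }
  return 0.0;
}

// d a / d V_i  (only nonzero entry of D1 h, at (0,0))
static double d1a_c(int kind, const double *kp, const double *xi,
                    const double *xj) {
  switch (kind) {
  case 1: return -xj[5];
  case 2: return -xj[6];
  case 3: return -1.0;
  case 4: return -ftm_gamma(xj[0], kp[1], kp[2]);
  case 5: return 0.0;
  default: stop("unknown coupling kind");
  }
  return 0.0;
}

// D2 h: single nonzero entry at (0, idx); returns value, sets idx
static double d2a_c(int kind, const double *kp, const double *xi,
                    const double *xj, int &idx) {
  switch (kind) {
  case 1: idx = 5; return kp[0] - xi[0];
  case 2: idx = 6; return kp[0] - xi[0];
  case 3: idx = 0; return 1.0;
  case 4: {
    idx = 0;
    double G = ftm_gamma(xj[0], kp[1], kp[2]);
    return (kp[0] - xi[0]) * (-kp[1] * G * (1.0 - G));
  }
  case 5: idx = 0; return 1.0;
  default: stop("unknown coupling kind");
  }
  return 0.0;
}

// ---------------------------------------------------------------------------
// parsed network specification
// ---------------------------------------------------------------------------
struct LayerC {
  std::vector<double> A;   // N*N column-major, A[i + N*j] = weight j -> i
  double sigma, delta;
  int kind;
  std::vector<double> kp;
  int dsteps;              // delta / h
};

struct NetC {
  int N, n;
  std::vector<int> model;            // per node
  std::vector< std::vector<double> > params;
  std::vector<int> dim;              // native dims
  std::vector<LayerC> layers;
  // optional current pulse added to dx[0] of one node
  int pulse_node = -1;
  double pulse_on = 0.0, pulse_off = 0.0, pulse_amp = 0.0;
};

static NetC parse_net(const List &spec, double h) {
  NetC net;
  net.N = as<int>(spec["N"]);
  net.n = as<int>(spec["n"]);
  IntegerVector mod = spec["model"];
  List pars = spec["params"];
  for (int i = 0; i < net.N; ++i) {
    net.model.push_back(mod[i]);
    NumericVector pv = pars[i];
    net.params.push_back(std::vector<double>(pv.begin(), pv.end()));
    net.dim.push_back(model_dim_c(mod[i]));
  }
  List layers = spec["layers"];
  for (int k = 0; k < layers.size(); ++k) {
    List lay = layers[k];
    LayerC L;
    NumericMatrix A = lay["A"];
    if (A.nrow() != net.N || A.ncol() != net.N) stop("layer dimension mismatch");
    L.A.assign(A.begin(), A.end());
    L.sigma = as<double>(lay["sigma"]);
    L.delta = as<double>(lay["delta"]);
    L.kind = as<int>(lay["kind"]);
    NumericVector kp = lay["kparams"];
    L.kp.assign(kp.begin(), kp.end());
    if (L.delta < 0) stop("negative delay");
    double r = L.delta / h;
    L.dsteps = (int)std::lround(r);
    if (std::fabs(r - L.dsteps) > 1e-6)
      stop("delay is not an integer multiple of the step");
    if (L.delta > 0 && L.dsteps < 1) stop("positive delay smaller than step");
    net.layers.push_back(L);
  }
  if (spec.containsElementNamed("pulse")) {
    RObject po = spec["pulse"];
    if (!po.isNULL()) {
      List pl(po);
      net.pulse_node = as<int>(pl["node"]) - 1;
      net.pulse_on = as<double>(pl["onset"]);
      net.pulse_off = net.pulse_on + as<double>(pl["duration"]);
      net.pulse_amp = as<double>(pl["amplitude"]);
    }
  }
  return net;
}

// network RHS; ydel[k] points to the full delayed state vector for layer k
static void net_rhs(const NetC &net, double t, const double *y,
                    const std::vector<const double *> &ydel, double *dy) {
  const int n = net.n, N = net.N;
  for (int i = 0; i < N; ++i) {
    const double *xi = y + i * n;
    double *dxi = dy + i * n;
    for (int c = 0; c < n; ++c) dxi[c] = 0.0;
    model_rhs_c(net.model[i], net.params[i].data(), xi, dxi);
    for (int c = net.dim[i]; c < n; ++c) dxi[c] = 0.0;
  }
  for (size_t k = 0; k < net.layers.size(); ++k) {
    const LayerC &L = net.layers[k];
    const double *yk = ydel[k];
    for (int i = 0; i < N; ++i) {
      const double *xi = y + i * n;
      double acc = 0.0;
      for (int j = 0; j < N; ++j) {
        double w = L.A[i + N * j];
        if (w != 0.0) acc += w * activation_c(L.kind, L.kp.data(), xi, yk + j * n);
      }
      dy[i * n] += L.sigma * acc;
    }
  }
  if (net.pulse_node >= 0 && t >= net.pulse_on && t < net.pulse_off)
    dy[net.pulse_node * net.n] += net.pulse_amp;
}

// ---------------------------------------------------------------------------
// uniform-grid ring-buffer history with cubic Hermite interpolation
// ---------------------------------------------------------------------------
struct History {
  int D, cap;
  double t0, h;
  long nstored = 0;          // points stored (grid indices 0..nstored-1)
  std::vector<double> Y, F;  // cap * D
  std::vector<double> y_init; // constant pre-history

  void init(int D_, int cap_, double t0_, double h_, const double *y0) {
    D = D_; cap = cap_; t0 = t0_; h = h_;
    Y.assign((size_t)cap * D, 0.0);
    F.assign((size_t)cap * D, 0.0);
    y_init.assign(y0, y0 + D);
  }
  void push(const double *y, const double *f) {
    size_t slot = (size_t)(nstored % cap) * D;
    std::memcpy(&Y[slot], y, sizeof(double) * D);
    std::memcpy(&F[slot], f, sizeof(double) * D);
    ++nstored;
  }
  // interpolate state at time t into out
  void eval(double t, double *out) const {
    if (t <= t0 + 1e-12 * std::max(1.0, std::fabs(t0))) {
      std::memcpy(out, y_init.data(), sizeof(double) * D);
      return;
    }
    double s = (t - t0) / h;
    long i = (long)std::floor(s + 1e-9);
    double th = s - i;
    if (i >= nstored - 1 && th < 1e-9) { i = nstored - 1; th = 0.0; }
    if (i < 0) { std::memcpy(out, y_init.data(), sizeof(double) * D); return; }
    if (i > nstored - 1) stop("history lookup beyond stored range");
    if (i > nstored - 2 && th > 1e-9) stop("history lookup needs future point");
    long imin = nstored - cap; if (imin < 0) imin = 0;
    if (i < imin) stop("history lookup older than ring capacity");
    const double *y0p = &Y[(size_t)(i % cap) * D];
    if (th <= 1e-9) { std::memcpy(out, y0p, sizeof(double) * D); return; }
    const double *f0p = &F[(size_t)(i % cap) * D];
    const double *y1p = &Y[(size_t)((i + 1) % cap) * D];
    const double *f1p = &F[(size_t)((i + 1) % cap) * D];
    double t2 = th * th, t3 = t2 * th;
    double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + th,
      h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
    for (int d = 0; d < D; ++d)
      out[d] = h00 * y0p[d] + h10 * h * f0p[d] + h01 * y1p[d] + h11 * h * f1p[d];
  }
};

// ---------------------------------------------------------------------------
// network integration (RK4 method of steps)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List net_integrate_cpp(List spec, NumericVector y0, double t0, double t1,
                       double h, int save_every, double store_from) {
  NetC net = parse_net(spec, h);
  const int D = net.N * net.n;
  if (y0.size() != D) stop("state length mismatch");
  long nsteps = (long)std::lround((t1 - t0) / h);
  if (nsteps < 1) stop("empty time span");
  int maxd = 1;
  bool any_delay = false;
  for (auto &L : net.layers) {
    if (L.dsteps > maxd) maxd = L.dsteps;
    if (L.dsteps > 0) any_delay = true;
  }
  History hist;
  hist.init(D, maxd + 3, t0, h, &y0[0]);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(D), k2(D), k3(D), k4(D), ytmp(D);
  const int nL = net.layers.size();
  std::vector< std::vector<double> > dbuf(nL, std::vector<double>(D));
  std::vector<const double *> ydel(nL);

  // saved output
  long save_start = (long)std::lround((store_from - t0) / h);
  if (save_start < 0) save_start = 0;
  long nsaved_max = (nsteps - save_start) / save_every + 2;
  std::vector<double> Ts; Ts.reserve(nsaved_max);
  std::vector<double> Ys, Fs;
  Ys.reserve((size_t)nsaved_max * D); Fs.reserve((size_t)nsaved_max * D);

  double blow_time = NA_REAL;
  int status = 0;

  auto delayed = [&](double tq, int stage_c, const double *ystage) {
    // fill ydel pointers for time tq (stage time); zero-delay layers use
    // the current stage state
    for (int k = 0; k < nL; ++k) {
      const LayerC &L = net.layers[k];
      if (L.dsteps == 0) ydel[k] = ystage;
      else {
        hist.eval(tq - L.delta, dbuf[k].data());
        ydel[k] = dbuf[k].data();
      }
    }
    (void)stage_c;
  };

  long step = 0;
  for (; step < nsteps; ++step) {
    double t = t0 + step * h;
    // k1 at t (also the grid derivative for Hermite history)
    delayed(t, 0, y.data());
    net_rhs(net, t, y.data(), ydel, k1.data());
    if (any_delay) hist.push(y.data(), k1.data());
    // save
    if (step >= save_start && (step - save_start) % save_every == 0) {
      Ts.push_back(t);
      Ys.insert(Ys.end(), y.begin(), y.end());
      Fs.insert(Fs.end(), k1.begin(), k1.end());
    }
    // stages
    for (int d = 0; d < D; ++d) ytmp[d] = y[d] + 0.5 * h * k1[d];
    delayed(t + 0.5 * h, 1, ytmp.data());
    net_rhs(net, t + 0.5 * h, ytmp.data(), ydel, k2.data());
    for (int d = 0; d < D; ++d) ytmp[d] = y[d] + 0.5 * h * k2[d];
    delayed(t + 0.5 * h, 2, ytmp.data());
    net_rhs(net, t + 0.5 * h, ytmp.data(), ydel, k3.data());
    for (int d = 0; d < D; ++d) ytmp[d] = y[d] + h * k3[d];
    delayed(t + h, 3, ytmp.data());
    net_rhs(net, t + h, ytmp.data(), ydel, k4.data());
    bool bad = false;
    for (int d = 0; d < D; ++d) {
      y[d] += h / 6.0 * (k1[d] + 2 * k2[d] + 2 * k3[d] + k4[d]);
      if (!std::isfinite(y[d])) bad = true;
    }
    if (bad) { status = 1; blow_time = t + h; break; }
  }

  // final point
  if (status == 0) {
    double tend = t0 + nsteps * h;
    delayed(tend, 0, y.data());
    net_rhs(net, tend, y.data(), ydel, k1.data());
    long stepn = nsteps;
    if (stepn >= save_start && (stepn - save_start) % save_every == 0) {
      Ts.push_back(tend);
      Ys.insert(Ys.end(), y.begin(), y.end());
      Fs.insert(Fs.end(), k1.begin(), k1.end());
    }
  }

  int T = Ts.size();
  NumericMatrix Ym(T, D), Fm(T, D);
  for (int r = 0; r < T; ++r)
    for (int d = 0; d < D; ++d) {
      Ym(r, d) = Ys[(size_t)r * D + d];
      Fm(r, d) = Fs[(size_t)r * D + d];
    }
  return List::create(_["times"] = NumericVector(Ts.begin(), Ts.end()),
                      _["Y"] = Ym, _["F"] = Fm,
                      _["final"] = NumericVector(y.begin(), y.end()),
                      _["status"] = status, _["blow_time"] = blow_time);
}

// single RHS evaluation (testing): delayed states supplied per layer
// [[Rcpp::export]]
NumericVector net_rhs_cpp(List spec, NumericVector y, List ydelayed, double t) {
  NetC net = parse_net(spec, 1.0);
  const int D = net.N * net.n;
  if (y.size() != D) stop("state length mismatch");
  std::vector< std::vector<double> > dbuf;
  std::vector<const double *> ydel;
  for (int k = 0; k < (int)net.layers.size(); ++k) {
    NumericVector v = ydelayed[k];
    dbuf.push_back(std::vector<double>(v.begin(), v.end()));
  }
  for (auto &b : dbuf) ydel.push_back(b.data());
  NumericVector out(D);
  net_rhs(net, t, &y[0], ydel, &out[0]);
  return out;
}

// [[Rcpp::export]]
NumericVector model_rhs_cpp(int id, NumericVector x, NumericVector params) {
  int n = model_dim_c(id);
  NumericVector out(n);
  model_rhs_c(id, &params[0], &x[0], &out[0]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix model_jac_cpp(int id, NumericVector x, NumericVector params) {
  int n = model_dim_c(id);
  NumericMatrix J(n, n);
  model_jac_c(id, &params[0], &x[0], &J[0], n);
  return J;
}

// [[Rcpp::export]]
NumericVector coupling_eval_cpp(int kind, NumericVector kparams,
                                NumericVector xi, NumericVector xj) {
  // returns c(a, d1a, d2a_value, d2a_index1based)
  int idx;
  std::vector<double> kp(kparams.begin(), kparams.end());
  double a = activation_c(kind, kp.data(), &xi[0], &xj[0]);
  double d1 = d1a_c(kind, kp.data(), &xi[0], &xj[0]);
  double d2 = d2a_c(kind, kp.data(), &xi[0], &xj[0], idx);
  return NumericVector::create(a, d1, d2, idx + 1.0);
}

// ---------------------------------------------------------------------------
// variational (transverse perturbation) integration
// ---------------------------------------------------------------------------
// vspec fields:
//  nb            number of transverse rows in the block
//  n             padded state dimension
//  Q             number of clusters in the quotient
//  row_cluster   length-nb, 1-based cluster index of each transverse row
//  cluster_model, cluster_params, cluster_dim : per cluster
//  layers: list of (tau nb x nb, R Q x Q, sigma, delta, kind, kparams)
// traj fields: t_start, dt, Y (T x Q*n), F (T x Q*n)  [uniform grid]

struct TrajC {
  double t_start, dt;
  int T, D;
  const double *Y, *F;
  void eval(double t, double *out) const {
    double s = (t - t_start) / dt;
    long i = (long)std::floor(s + 1e-9);
    double th = s - i;
    if (i < 0) {
      if (i < -1 || th < 0.999) stop("trajectory lookup before start");
      i = 0; th = 0.0;
    }
    if (i >= T - 1) {
      if (i > T - 1 || th > 1e-9) {
        if (i == T - 1 && th <= 1e-6) th = 0.0;
        else stop("trajectory lookup beyond end");
      }
      if (i > T - 1) { i = T - 1; th = 0.0; }
    }
    if (th <= 1e-9) {
      for (int d = 0; d < D; ++d) out[d] = Y[i + (size_t)T * d];
      return;
    }
    double t2 = th * th, t3 = t2 * th;
    double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + th,
      h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
    for (int d = 0; d < D; ++d) {
      double y0 = Y[i + (size_t)T * d], y1 = Y[i + 1 + (size_t)T * d];
      double f0 = F[i + (size_t)T * d], f1 = F[i + 1 + (size_t)T * d];
      out[d] = h00 * y0 + h10 * dt * f0 + h01 * y1 + h11 * dt * f1;
    }
  }
};

struct VarC {
  int nb, n, Q;
  std::vector<int> row_cluster;   // 0-based
  std::vector<int> cmodel;
  std::vector< std::vector<double> > cparams;
  std::vector<int> cdim;
  struct VLayer {
    std::vector<double> tau;  // nb*nb col-major
    std::vector<double> R;    // Q*Q col-major
    double sigma, delta; int kind;
    std::vector<double> kp;
    int dsteps;
  };
  std::vector<VLayer> layers;
};

static VarC parse_var(const List &vs, double h) {
  VarC v;
  v.nb = as<int>(vs["nb"]); v.n = as<int>(vs["n"]); v.Q = as<int>(vs["Q"]);
  IntegerVector rc = vs["row_cluster"];
  for (int i = 0; i < v.nb; ++i) v.row_cluster.push_back(rc[i] - 1);
  IntegerVector cm = vs["cluster_model"];
  List cp = vs["cluster_params"];
  IntegerVector cd = vs["cluster_dim"];
  for (int q = 0; q < v.Q; ++q) {
    v.cmodel.push_back(cm[q]);
    NumericVector pv = cp[q];
    v.cparams.push_back(std::vector<double>(pv.begin(), pv.end()));
    v.cdim.push_back(cd[q]);
  }
  List layers = vs["layers"];
  for (int k = 0; k < layers.size(); ++k) {
    List lay = layers[k];
    VarC::VLayer L;
    NumericMatrix tau = lay["tau"]; L.tau.assign(tau.begin(), tau.end());
    NumericMatrix R = lay["R"]; L.R.assign(R.begin(), R.end());
    L.sigma = as<double>(lay["sigma"]);
    L.delta = as<double>(lay["delta"]);
    L.kind = as<int>(lay["kind"]);
    NumericVector kp = lay["kparams"]; L.kp.assign(kp.begin(), kp.end());
    double r = L.delta / h;
    L.dsteps = (int)std::lround(r);
    if (std::fabs(r - L.dsteps) > 1e-6)
      stop("delay is not an integer multiple of the step");
    v.layers.push_back(L);
  }
  return v;
}

// variational RHS at time t:
//   eta_dot_r = P1_{q(r)}(t) eta_r
//             + sum_k sigma^k sum_r' tau^k[r,r'] D2h^k(s_{q(r)}(t), s_{q(r')}(t - d_k)) eta_r'(t - d_k)
// where P1_q(t) = Df_q(s_q(t)) + e00 * sum_k sigma^k sum_p R^k[q,p] d1a^k(s_q(t), s_p(t - d_k))
struct VarWork {
  std::vector<double> s_now;                    // Q*n
  std::vector< std::vector<double> > s_del;     // per layer, Q*n
  std::vector<double> P1;                       // Q * n * n
  std::vector<double> etadelbuf;                // per layer eta, filled outside
};

static void var_coeffs(const VarC &v, const TrajC &traj, double t, VarWork &w) {
  const int n = v.n, Q = v.Q;
  traj.eval(t, w.s_now.data());
  for (size_t k = 0; k < v.layers.size(); ++k) {
    if (v.layers[k].dsteps == 0)
      std::memcpy(w.s_del[k].data(), w.s_now.data(), sizeof(double) * Q * n);
    else traj.eval(t - v.layers[k].delta, w.s_del[k].data());
  }
  // P1 blocks
  for (int q = 0; q < Q; ++q) {
    double *J = &w.P1[(size_t)q * n * n];
    for (int d = 0; d < n * n; ++d) J[d] = 0.0;
    model_jac_c(v.cmodel[q], v.cparams[q].data(), &w.s_now[(size_t)q * n], J, n);
    double acc = 0.0;
    for (size_t k = 0; k < v.layers.size(); ++k) {
      const VarC::VLayer &L = v.layers[k];
      double lacc = 0.0;
      for (int p = 0; p < Q; ++p) {
        double rw = L.R[q + Q * p];
        if (rw != 0.0)
          lacc += rw * d1a_c(L.kind, L.kp.data(), &w.s_now[(size_t)q * n],
                             &w.s_del[k][(size_t)p * n]);
      }
      acc += L.sigma * lacc;
    }
    J[0] += acc;
    // padding: zero rows/cols beyond native dim
    for (int d = v.cdim[q]; d < n; ++d)
      for (int e = 0; e < n; ++e) { J[d + n * e] = 0.0; J[e + n * d] = 0.0; }
  }
}

// eta, etadel[k]: nb*n
static void var_rhs(const VarC &v, const VarWork &w, const double *eta,
                    const std::vector<const double *> &etadel, double *deta) {
  const int n = v.n, nb = v.nb;
  for (int r = 0; r < nb; ++r) {
    int q = v.row_cluster[r];
    const double *J = &w.P1[(size_t)q * n * n];
    const double *er = eta + (size_t)r * n;
    double *dr = deta + (size_t)r * n;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += J[i + n * j] * er[j];
      dr[i] = s;
    }
    // delayed coupling (lands on component 0 only)
    for (size_t k = 0; k < v.layers.size(); ++k) {
      const VarC::VLayer &L = v.layers[k];
      const double *ed = etadel[k];
      double acc = 0.0;
      for (int r2 = 0; r2 < nb; ++r2) {
        double tw = L.tau[r + nb * r2];
        if (tw != 0.0) {
          int q2 = v.row_cluster[r2];
          int idx;
          double d2 = d2a_c(L.kind, L.kp.data(), &w.s_now[(size_t)q * n],
                            &w.s_del[k][(size_t)q2 * n], idx);
          acc += tw * d2 * ed[(size_t)r2 * n + idx];
        }
      }
      dr[0] += L.sigma * acc;
    }
    for (int d = v.cdim[q]; d < n; ++d) dr[d] = 0.0;
  }
}

// [[Rcpp::export]]
List var_integrate_cpp(List vspec, List traj, NumericVector eta0,
                       double t0, double t1, double h,
                       double eps_hi, double eps_lo, int sample_every) {
  VarC v = parse_var(vspec, h);
  TrajC tr;
  tr.t_start = as<double>(traj["t_start"]);
  tr.dt = as<double>(traj["dt"]);
  NumericMatrix Y = traj["Y"], F = traj["F"];
  tr.T = Y.nrow(); tr.D = Y.ncol();
  if (tr.D != v.Q * v.n) stop("trajectory dimension mismatch");
  tr.Y = &Y[0]; tr.F = &F[0];

  const int D = v.nb * v.n;
  if (eta0.size() != D) stop("eta0 length mismatch");
  long nsteps = (long)std::lround((t1 - t0) / h);
  int maxd = 1; bool any_delay = false;
  for (auto &L : v.layers) {
    if (L.dsteps > maxd) maxd = L.dsteps;
    if (L.dsteps > 0) any_delay = true;
  }
  std::vector<double> eta(eta0.begin(), eta0.end());
  // apply padding mask
  for (int r = 0; r < v.nb; ++r)
    for (int d = v.cdim[v.row_cluster[r]]; d < v.n; ++d) eta[(size_t)r * v.n + d] = 0.0;

  History hist;
  hist.init(D, maxd + 3, t0, h, eta.data());

  VarWork w;
  w.s_now.assign((size_t)v.Q * v.n, 0.0);
  for (size_t k = 0; k < v.layers.size(); ++k)
    w.s_del.push_back(std::vector<double>((size_t)v.Q * v.n, 0.0));
  w.P1.assign((size_t)v.Q * v.n * v.n, 0.0);

  std::vector<double> k1(D), k2(D), k3(D), k4(D), ytmp(D);
  const int nL = v.layers.size();
  std::vector< std::vector<double> > dbuf(nL, std::vector<double>(D));
  std::vector<const double *> edel(nL);

  std::vector<double> sample_t, sample_ln;
  sample_t.reserve(nsteps / sample_every + 2);
  sample_ln.reserve(nsteps / sample_every + 2);

  auto delayed = [&](double tq, const double *estage) {
    for (int k = 0; k < nL; ++k) {
      if (v.layers[k].dsteps == 0) edel[k] = estage;
      else { hist.eval(tq - v.layers[k].delta, dbuf[k].data()); edel[k] = dbuf[k].data(); }
    }
  };
  auto norm2 = [&](const double *e) {
    double s = 0.0;
    for (int d = 0; d < D; ++d) s += e[d] * e[d];
    return std::sqrt(s);
  };

  int stop_code = 0;  // 0 tmax, 1 hi, 2 lo, 3 blow-up
  double stop_time = t1;
  long step = 0;
  for (; step < nsteps; ++step) {
    double t = t0 + step * h;
    var_coeffs(v, tr, t, w);
    delayed(t, eta.data());
    var_rhs(v, w, eta.data(), edel, k1.data());
    if (any_delay) hist.push(eta.data(), k1.data());
    if (step % sample_every == 0) {
      double nm = norm2(eta.data());
      sample_t.push_back(t);
      sample_ln.push_back(std::log(nm));
      if (nm >= eps_hi) { stop_code = 1; stop_time = t; break; }
      if (nm <= eps_lo) { stop_code = 2; stop_time = t; break; }
    }
    for (int d = 0; d < D; ++d) ytmp[d] = eta[d] + 0.5 * h * k1[d];
    var_coeffs(v, tr, t + 0.5 * h, w);
    delayed(t + 0.5 * h, ytmp.data());
    var_rhs(v, w, ytmp.data(), edel, k2.data());
    for (int d = 0; d < D; ++d) ytmp[d] = eta[d] + 0.5 * h * k2[d];
    var_rhs(v, w, ytmp.data(), edel, k3.data());
    for (int d = 0; d < D; ++d) ytmp[d] = eta[d] + h * k3[d];
    var_coeffs(v, tr, t + h, w);
    delayed(t + h, ytmp.data());
    var_rhs(v, w, ytmp.data(), edel, k4.data());
    bool bad = false;
    for (int d = 0; d < D; ++d) {
      eta[d] += h / 6.0 * (k1[d] + 2 * k2[d] + 2 * k3[d] + k4[d]);
      if (!std::isfinite(eta[d])) bad = true;
    }
    if (bad) { stop_code = 3; stop_time = t + h; break; }
  }
  if (stop_code == 0) {
    double nm = norm2(eta.data());
    sample_t.push_back(t0 + nsteps * h);
    sample_ln.push_back(std::log(nm));
  }
  return List::create(_["sample_t"] = NumericVector(sample_t.begin(), sample_t.end()),
                      _["sample_ln"] = NumericVector(sample_ln.begin(), sample_ln.end()),
                      _["stop_code"] = stop_code, _["stop_time"] = stop_time,
                      _["eta"] = NumericVector(eta.begin(), eta.end()));
}
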