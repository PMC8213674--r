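// Exact samplers and the event-driven kinetic Monte Carlo engine.
//
// All first-passage and no-passage densities on intervals are evaluated from
// dual representations: pole (sine/cosine) series for moderate-to-long
// dimensionless times theta = D t / l^2, and image (Gaussian/erfc) series for
// short times. Both are exact to near machine precision in their regime; the
// switch point is chosen where both converge with a handful of terms.
//
// RNG: R's generator via unif_rand()/norm_rand(), so everything is
// reproducible from set.seed() on the R side.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <tuple>
using namespace Rcpp;

static const double PI_ = 3.141592653589793238462643383279502884;

// ---------------------------------------------------------------------------
// interval [0,1], absorbing both ends, start xi in (0,1): CDF of exit through
// side 0 by dimensionless time theta (unconditional; total mass 1 - xi)
static double itv_cdf_side0(double theta, double xi) {
  if (theta <= 0) return 0.0;
  if (theta < 0.045) {
    // image representation: sum_n sign(xi+2n) erfc(|xi+2n|/(2 sqrt(theta)))
    double w = 2.0 * std::sqrt(theta);
    double s = 0.0;
    for (int n = -4; n <= 4; ++n) {
      double a = xi + 2.0 * n;
      double t = std::erfc(std::fabs(a) / w);
      s += (a >= 0 ? t : -t);
    }
    return s;
  }
  // spectral: (1-xi) - sum_p (2/(p pi)) sin(p pi xi) exp(-p^2 pi^2 theta)
  double s = 1.0 - xi;
  for (int p = 1; p <= 64; ++p) {
    double lam = p * p * PI_ * PI_ * theta;
    if (lam > 46.0) break;
    s -= 2.0 / (p * PI_) * std::sin(p * PI_ * xi) * std::exp(-lam);
  }
  if (s < 0) s = 0;
  return s;
}

// survival in the interval at dimensionless time theta
static double itv_survival(double theta, double xi) {
  if (theta <= 0) return 1.0;
  if (theta < 0.045) {
    double s = 1.0 - itv_cdf_side0(theta, xi) - itv_cdf_side0(theta, 1.0 - xi);
    return s > 0 ? s : 0;
  }
  double s = 0.0;
  for (int p = 1; p <= 64; ++p) {
    double lam = p * p * PI_ * PI_ * theta;
    if (lam > 46.0) break;
    // integral of (2/l) sin(p pi x) sin(p pi xi) over x: (2/(p pi)) (1-cos(p pi)) sin(p pi xi)
    double c = 2.0 / (p * PI_) * (1.0 - std::cos(p * PI_)) * std::sin(p * PI_ * xi);
    s += c * std::exp(-lam);
  }
  if (s < 0) s = 0;
  if (s > 1) s = 1;
  return s;
}

// sample exit time (dimensionless) through side 0 given exit is at side 0;
// i.e. solve itv_cdf_side0(theta, xi) = U * (1 - xi) by bisection in log theta
static double itv_sample_theta(double xi, double U) {
  double target = U * (1.0 - xi);
  double lo = std::log(std::max(1e-300, xi * xi / 330.0));
  double hi = std::log(25.0);
  // expand hi if needed (target very close to total mass)
  while (itv_cdf_side0(std::exp(hi), xi) < target && hi < 60) hi += 2.0;
  for (int it = 0; it < 90; ++it) {
    double mid = 0.5 * (lo + hi);
    if (itv_cdf_side0(std::exp(mid), xi) < target) lo = mid; else hi = mid;
    if (hi - lo < 1e-13) break;
  }
  return std::exp(0.5 * (lo + hi));
}

// sample (side, dt) of first exit from [0,l], start x0, diffusivity D
static void itv_exit_sample(double l, double x0, double D, int &side, double &dt) {
  double xi = x0 / l;
  if (xi < 1e-14) { side = 0; dt = 0.0; return; }
  if (xi > 1 - 1e-14) { side = 1; dt = 0.0; return; }
  double U1 = unif_rand();
  double th;
  if (U1 < 1.0 - xi) { side = 0; th = itv_sample_theta(xi, unif_rand()); }
  else { side = 1; th = itv_sample_theta(1.0 - xi, unif_rand()); }
  dt = th * l * l / D;
}

// normal pdf with variance v
static inline double gpdf(double z, double v) {
  return std::exp(-z * z / (2.0 * v)) / std::sqrt(2.0 * PI_ * v);
}

// no-passage position in [0,l] (two absorbing ends), start x0, elapsed dt
static double itv_nopass_sample(double l, double x0, double D, double dt) {
  double xi = x0 / l;
  double theta = D * dt / (l * l);
  if (theta <= 1e-14) return x0;
  if (theta < 0.045) {
    // rejection from the free Gaussian with image correction
    double v = 2.0 * D * dt;
    for (int tries = 0; tries < 10000; ++tries) {
      double y = x0 + norm_rand() * std::sqrt(v);
      if (y <= 0 || y >= l) continue;
      double num = 0.0;
      for (int n = -3; n <= 3; ++n)
        num += gpdf(y - x0 - 2.0 * n * l, v) - gpdf(y + x0 - 2.0 * n * l, v);
      double acc = num / gpdf(y - x0, v);
      if (acc > 0 && unif_rand() < acc) return y;
    }
    return x0; // unreachable in practice
  }
  // spectral CDF bisection
  double S = itv_survival(theta, xi);
  if (S <= 0) return x0;
  double U = unif_rand() * S;
  // cumulative: G(x) = sum_p (2/(p pi)) sin(p pi xi) e^{-p^2pi^2 theta} (1 - cos(p pi x/l))
  double lo = 0, hi = l;
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    double g = 0.0;
    for (int p = 1; p <= 64; ++p) {
      double lam = p * p * PI_ * PI_ * theta;
      if (lam > 46.0) break;
      g += 2.0 / (p * PI_) * std::sin(p * PI_ * xi) * std::exp(-lam) *
        (1.0 - std::cos(p * PI_ * mid / l));
    }
    if (g < U) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// ---------------------------------------------------------------------------
// reflecting origin, absorbing at L, start at 0 (also the symmetric
// node-segment domain folded to its radial coordinate)
static double refl_cdf(double theta) { // P(exit by theta), theta = D t / L^2
  if (theta <= 0) return 0.0;
  if (theta < 0.1) {
    double w = 2.0 * std::sqrt(theta);
    double s = 0.0;
    for (int k = 0; k <= 6; ++k) {
      double t = std::erfc((2.0 * k + 1.0) / w);
      if (t == 0) break;
      s += (k % 2 == 0 ? 2.0 : -2.0) * t;
    }
    return s < 0 ? 0 : s;
  }
  double s = 1.0;
  for (int p = 1; p <= 64; ++p) {
    double q = 2.0 * p - 1.0;
    double lam = q * q * PI_ * PI_ * theta / 4.0;
    if (lam > 46.0) break;
    s -= (p % 2 == 1 ? 4.0 : -4.0) / (q * PI_) * std::exp(-lam);
  }
  return std::min(std::max(s, 0.0), 1.0);
}

static double refl_sample_theta(double U) {
  double lo = std::log(1.0 / 330.0), hi = std::log(25.0);
  while (refl_cdf(std::exp(hi)) < U && hi < 60) hi += 2.0;
  for (int it = 0; it < 90; ++it) {
    double mid = 0.5 * (lo + hi);
    if (refl_cdf(std::exp(mid)) < U) lo = mid; else hi = mid;
    if (hi - lo < 1e-13) break;
  }
  return std::exp(0.5 * (lo + hi));
}

// radial no-passage position for the reflecting/absorbing interval, start 0
static double refl_nopass_sample(double L, double D, double dt) {
  double theta = D * dt / (L * L);
  if (theta <= 1e-14) return 0.0;
  if (theta < 0.1) {
    double v = 2.0 * D * dt;
    for (int tries = 0; tries < 10000; ++tries) {
      double r = std::fabs(norm_rand()) * std::sqrt(v);
      if (r >= L) continue;
      double num = 0.0;
      for (int n = -3; n <= 3; ++n)
        num += (n % 2 == 0 ? 1.0 : -1.0) * gpdf(r - 2.0 * n * L, v);
      double acc = num / gpdf(r, v);
      if (acc > 0 && unif_rand() < acc) return r;
    }
    return 0.0;
  }
  // spectral: c(r) ~ sum_p cos(u_p r) e^{-D u_p^2 t}, u_p = (2p-1) pi / (2L)
  double S = 0.0;
  double coef[64]; double up[64]; int np = 0;
  for (int p = 1; p <= 64; ++p) {
    double u = (2.0 * p - 1.0) * PI_ / (2.0 * L);
    double lam = D * u * u * dt;
    if (lam > 46.0) break;
    up[np] = u; coef[np] = std::exp(-lam);
    S += coef[np] * std::sin(u * L) / u; // = coef * (+-1)/u
    np++;
  }
  if (np == 0 || S <= 0) return 0.0;
  double U = unif_rand() * S;
  double lo = 0, hi = L;
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    double g = 0.0;
    for (int p = 0; p < np; ++p) g += coef[p] * std::sin(up[p] * mid) / up[p];
    if (g < U) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// ---------------------------------------------------------------------------
// node-neighborhood class tables
struct NbhdClass {
  std::vector<double> u, du2;     // poles, D u^2
  std::vector<std::vector<double> > R; // residues per slot [d][P]
  std::vector<double> Pstar, lens;
  std::vector<double> tg;         // time grid
  std::vector<std::vector<double> > cdfg; // conditional CDF per slot [d][G]
  double D;
  int d;
};

static NbhdClass make_class(List cls, double D) {
  NbhdClass c;
  c.D = D;
  NumericVector u = cls["u"];
  NumericMatrix R = cls["R"];
  NumericVector Ps = cls["Pstar"];
  NumericVector lens = cls["lens"];
  NumericVector tg = cls["t_grid"];
  NumericMatrix cg = cls["cdf_grid"];
  c.u.assign(u.begin(), u.end());
  c.du2.resize(u.size());
  for (int i = 0; i < u.size(); ++i) c.du2[i] = D * u[i] * u[i];
  c.d = Ps.size();
  c.R.resize(c.d);
  for (int k = 0; k < c.d; ++k) {
    c.R[k].resize(R.nrow());
    for (int p = 0; p < R.nrow(); ++p) c.R[k][p] = R(p, k);
  }
  c.Pstar.assign(Ps.begin(), Ps.end());
  c.lens.assign(lens.begin(), lens.end());
  c.tg.assign(tg.begin(), tg.end());
  c.cdfg.resize(c.d);
  for (int k = 0; k < c.d; ++k) {
    c.cdfg[k].resize(cg.nrow());
    for (int i = 0; i < cg.nrow(); ++i) c.cdfg[k][i] = cg(i, k);
  }
  return c;
}

// conditional exit-time CDF through slot k (exact series)
static double nbhd_cdf(const NbhdClass &c, int k, double t) {
  double s = 0.0;
  size_t P = c.u.size();
  for (size_t p = 0; p < P; ++p) {
    double lam = c.du2[p] * t;
    if (lam > 46.0) break;
    s += c.R[k][p] / c.du2[p] * std::exp(-lam);
  }
  double F = 1.0 - s / c.Pstar[k];
  return std::min(std::max(F, 0.0), 1.0);
}

// sample (slot, dt) for exit from a node-neighborhood
static void nbhd_exit_sample(const NbhdClass &c, int &slot, double &dt) {
  double U = unif_rand();
  int k = c.d - 1;
  double acc = 0.0;
  for (int j = 0; j < c.d; ++j) { acc += c.Pstar[j]; if (U <= acc) { k = j; break; } }
  slot = k;
  double U2 = unif_rand();
  const std::vector<double> &cg = c.cdfg[k];
  int G = cg.size();
  // bracket from the table
  int lo_i = 0, hi_i = G - 1;
  if (U2 <= cg[0]) { dt = c.tg[0]; return; }
  if (U2 >= cg[G - 1]) {
    // extend beyond the grid: asymptotic single-pole tail
    double lo = c.tg[G - 1], hi = c.tg[G - 1] * 2.0;
    while (nbhd_cdf(c, k, hi) < U2 && hi < c.tg[G - 1] * 1e6) hi *= 2.0;
    for (int it = 0; it < 70; ++it) {
      double mid = 0.5 * (lo + hi);
      if (nbhd_cdf(c, k, mid) < U2) lo = mid; else hi = mid;
    }
    dt = 0.5 * (lo + hi);
    return;
  }
  while (hi_i - lo_i > 1) {
    int mid = (lo_i + hi_i) / 2;
    if (cg[mid] < U2) lo_i = mid; else hi_i = mid;
  }
  double lo = c.tg[std::max(0, lo_i - 1)], hi = c.tg[std::min(G - 1, hi_i + 1)];
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    if (nbhd_cdf(c, k, mid) < U2) lo = mid; else hi = mid;
    if ((hi - lo) < 1e-12 * hi) break;
  }
  dt = 0.5 * (lo + hi);
}

// no-passage within a neighborhood after elapsed dt: returns (slot, distance
// from center node r)
static void nbhd_nopass_sample(const NbhdClass &c, double dt, int &slot, double &r) {
  size_t P = c.u.size();
  double tshort = 46.0 / c.du2[P - 1];
  double minl = c.lens[0];
  for (int k = 1; k < c.d; ++k) minl = std::min(minl, c.lens[k]);
  if (dt < tshort) {
    // short-time: free half-Gaussian on a uniformly chosen arm
    for (int tries = 0; tries < 10000; ++tries) {
      int k = std::min((int)(unif_rand() * c.d), c.d - 1);
      double rr = std::fabs(norm_rand()) * std::sqrt(2.0 * c.D * dt);
      if (rr < c.lens[k]) { slot = k; r = rr; return; }
    }
    slot = 0; r = 0; return;
  }
  // edge weights Y_k(0, dt)
  std::vector<double> wk(c.d, 0.0);
  double tot = 0.0;
  for (int k = 0; k < c.d; ++k) {
    double s = 0.0;
    for (size_t p = 0; p < P; ++p) {
      double lam = c.du2[p] * dt;
      if (lam > 46.0) break;
      s += c.R[k][p] / c.du2[p] * (1.0 - std::cos(c.u[p] * c.lens[k])) *
        std::exp(-lam);
    }
    wk[k] = std::max(s, 0.0);
    tot += wk[k];
  }
  if (tot <= 0) { slot = 0; r = 0; return; }
  double U = unif_rand() * tot;
  int k = c.d - 1;
  double acc = 0;
  for (int j = 0; j < c.d; ++j) { acc += wk[j]; if (U <= acc) { k = j; break; } }
  slot = k;
  // position: bisection on Ycum(r) = Y_k(l-r .. l) mass within distance r
  double lk = c.lens[k];
  double U2 = unif_rand() * wk[k];
  double lo = 0, hi = lk;
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    double g = 0.0;
    for (size_t p = 0; p < P; ++p) {
      double lam = c.du2[p] * dt;
      if (lam > 46.0) break;
      g += c.R[k][p] / c.du2[p] *
        (std::cos(c.u[p] * (lk - mid)) - std::cos(c.u[p] * lk)) * std::exp(-lam);
    }
    if (g < U2) lo = mid; else hi = mid;
  }
  r = 0.5 * (lo + hi);
}

// ---------------------------------------------------------------------------
// thin R-facing wrappers over the scalar samplers

// [[Rcpp::export]]
List cpp_interval_sample_exit(double l, double x0, double D, int n) {
  IntegerVector side(n); NumericVector dt(n);
  for (int i = 0; i < n; ++i) {
    int s; double t;
    itv_exit_sample(l, x0, D, s, t);
    side[i] = s; dt[i] = t;
  }
  return List::create(side, dt);
}

// [[Rcpp::export]]
NumericVector cpp_interval_sample_nopassage(double l, double x0, double D,
                                            double dt, int n) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = itv_nopass_sample(l, x0, D, dt);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_refl_sample_exit(double L, double D, int n) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = refl_sample_theta(unif_rand()) * L * L / D;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_refl_sample_nopassage(double L, double D, double dt, int n) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = refl_nopass_sample(L, D, dt);
  return out;
}

// [[Rcpp::export]]
List cpp_nbhd_sample_exit(NumericVector u, NumericMatrix R, NumericVector Pstar,
                          double D, NumericVector t_grid, NumericMatrix cdf_grid,
                          int n) {
  List cls = List::create(_["u"] = u, _["R"] = R, _["Pstar"] = Pstar,
                          _["lens"] = NumericVector(Pstar.size(), 1.0),
                          _["t_grid"] = t_grid, _["cdf_grid"] = cdf_grid);
  NbhdClass c = make_class(cls, D);
  IntegerVector slot(n); NumericVector dt(n);
  for (int i = 0; i < n; ++i) {
    int k; double t;
    nbhd_exit_sample(c, k, t);
    slot[i] = k + 1; dt[i] = t;
  }
  return List::create(slot, dt);
}

// [[Rcpp::export]]
List cpp_nbhd_sample_nopassage(NumericVector u, NumericMatrix R,
                               NumericVector lens, double D, double dt, int n) {
  NumericVector Ps(lens.size());
  { // splitting probabilities just for the struct (weights recomputed inside)
    double s = 0;
    for (int k = 0; k < lens.size(); ++k) { Ps[k] = 1.0 / lens[k]; s += Ps[k]; }
    for (int k = 0; k < lens.size(); ++k) Ps[k] /= s;
  }
  NumericVector tg = NumericVector::create(1.0);
  NumericMatrix cg(1, lens.size());
  List cls = List::create(_["u"] = u, _["R"] = R, _["Pstar"] = Ps,
                          _["lens"] = lens, _["t_grid"] = tg, _["cdf_grid"] = cg);
  NbhdClass c = make_class(cls, D);
  IntegerVector slot(n); NumericVector r(n);
  for (int i = 0; i < n; ++i) {
    int k; double rr;
    nbhd_nopass_sample(c, dt, k, rr);
    slot[i] = k + 1; r[i] = rr;
  }
  return List::create(slot, r);
}

// ---------------------------------------------------------------------------
// event-driven multi-particle engine

struct Net {
  int n, E;
  std::vector<int> deg, adj_ptr, adj_edge, adj_opp, adj_slot;
  std::vector<int> efrom, eto;
  std::vector<double> elen;
  std::vector<int> nclass;
  std::vector<char> is_target;
  // slot of node v within edge e's endpoints handled via efrom/eto
  int slot_of(int v, int e) const { // adjacency slot index of edge e at node v
    for (int a = adj_ptr[v]; a < adj_ptr[v + 1]; ++a)
      if (adj_edge[a] == e) return a - adj_ptr[v];
    return -1;
  }
};

enum DomType { DNONE = -1, DNBHD = 0, DNSEG = 1, DESEG = 2, DPAIR = 3 };

struct Particle {
  int status = 0;         // 0 free, 1 absorbed, 2 stopped
  bool on_node = false;
  int node = -1, edge = -1;
  double x = 0;           // coordinate from efrom
  double t = 0;
  int dtype = DNONE;
  int dcenter = -1;       // NBHD / NSEG center
  double arm = 0;         // NSEG
  int dedge = -1; double dlo = 0, dhi = 0; // ESEG / PAIR segment
  int partner = -1;       // PAIR
  bool pair_primary = false;
  double w0 = 0, wmax = 0, v0 = 0, vlo = 0, vhi = 0, t0 = 0; // PAIR box
  int evt_coord = 0, evt_side = 0, evt_slot = 0;
  double evt_t = 0;
  long version = 0;
};

struct Engine {
  const Net *net;
  const std::vector<NbhdClass> *classes;
  double D;
  std::vector<Particle> P;
  typedef std::tuple<double, int, long> Ev;
  std::priority_queue<Ev, std::vector<Ev>, std::greater<Ev> > queue;
  double enc_time = -1;
  int rule; // 0 encounter, 1 targets
  // particles interact (mutually exclusive domains, pair propagation) only
  // under the encounter rule; target-search particles are independent and
  // must reproduce single-particle marginals exactly
  bool interacting() const { return rule == 0; }
  long n_events = 0;
  bool log_events = false;
  std::vector<double> event_times;
  static const double EPS;

  // --- geometry helpers -----------------------------------------------
  // interval occupied by particle q's domain on edge e, coords from efrom;
  // returns false if none
  bool dom_on_edge(int q, int e, double &a, double &b) const {
    const Particle &p = P[q];
    if (p.status != 0 || p.dtype == DNONE) return false;
    if (p.dtype == DNBHD) {
      int c = p.dcenter;
      for (int s = net->adj_ptr[c]; s < net->adj_ptr[c + 1]; ++s)
        if (net->adj_edge[s] == e) { a = 0; b = net->elen[e]; return true; }
      return false;
    }
    if (p.dtype == DNSEG) {
      int c = p.dcenter;
      for (int s = net->adj_ptr[c]; s < net->adj_ptr[c + 1]; ++s)
        if (net->adj_edge[s] == e) {
          if (net->efrom[e] == c) { a = 0; b = p.arm; }
          else { a = net->elen[e] - p.arm; b = net->elen[e]; }
          return true;
        }
      return false;
    }
    if (p.dedge == e) { a = p.dlo; b = p.dhi; return true; }
    return false;
  }

  // nearest free-space bounds around position x on edge e, ignoring
  // particles in set S (by flag)
  void free_bounds(int e, double x, const std::vector<char> &inS,
                   double &lo, double &hi) const {
    lo = 0; hi = net->elen[e];
    if (!interacting()) return;
    for (size_t q = 0; q < P.size(); ++q) {
      if (inS[q]) continue;
      double a, b;
      if (!dom_on_edge(q, e, a, b)) continue;
      if (b <= x + EPS && b > lo) lo = b;
      if (a >= x - EPS && a < hi) hi = a;
    }
  }

  // is node v blocked (some other free particle, not in S, sits at v, i.e.
  // has a node-centered domain there)?
  bool node_blocked(int v, const std::vector<char> &inS) const {
    if (!interacting()) return false;
    for (size_t q = 0; q < P.size(); ++q) {
      if (inS[q] || P[q].status != 0) continue;
      if (P[q].on_node && P[q].node == v) return true;
    }
    return false;
  }

  // --- event bookkeeping ----------------------------------------------
  void push_event(int i) {
    P[i].version++;
    queue.push(Ev(P[i].evt_t, i, P[i].version));
  }

  // --- domain construction --------------------------------------------
  void clear_domain(int i) { P[i].dtype = DNONE; P[i].version++; }

  void build_node_domain(int i, const std::vector<char> &inS, double tnow) {
    Particle &p = P[i];
    int v = p.node;
    int d = net->deg[v];
    double arm = 1e300;
    bool full = true;
    if (!interacting()) {
      p.dtype = DNBHD; p.dcenter = v;
      const NbhdClass &c = (*classes)[net->nclass[v]];
      int slot; double dt;
      nbhd_exit_sample(c, slot, dt);
      p.evt_slot = slot; p.evt_t = tnow + dt;
      push_event(i);
      return;
    }
    for (int s = net->adj_ptr[v]; s < net->adj_ptr[v + 1]; ++s) {
      int e = net->adj_edge[s];
      int u = net->adj_opp[s];
      double le = net->elen[e];
      bool from_side = (net->efrom[e] == v);
      double lim = le;
      // constraints from other particles' domains on this edge
      for (size_t q = 0; q < P.size(); ++q) {
        if ((int)q == i || P[q].status != 0) continue;
        double a, b;
        if (inS[q]) {
          // members of the rebuild set: constrain by half-distance to them
          const Particle &pq = P[q];
          if (!pq.on_node && pq.edge == e) {
            double gq = from_side ? pq.x : le - pq.x;
            lim = std::min(lim, gq / 2.0);
          } else if (pq.on_node && pq.node == u) {
            lim = std::min(lim, le / 2.0);
          }
          continue;
        }
        if (!dom_on_edge(q, e, a, b)) {
          // no domain interval on e; but a non-member at node u blocks full reach
          continue;
        }
        double near = from_side ? a : le - b; // distance from v to domain start
        double far = from_side ? b : le - a;
        if (far <= EPS) continue; // interval hugging the far end? keep lim
        lim = std::min(lim, near);
      }
      if (node_blocked(u, inS)) lim = std::min(lim, le); // boundary at u is fine? no:
      // a particle at u owns a node-centered domain; its arms give intervals,
      // handled above. u itself being its center means we cannot hop onto u:
      if (node_blocked(u, inS)) full = false;
      if (lim < le - EPS) full = false;
      arm = std::min(arm, lim);
    }
    if (full) {
      p.dtype = DNBHD; p.dcenter = v;
      const NbhdClass &c = (*classes)[net->nclass[v]];
      int slot; double dt;
      nbhd_exit_sample(c, slot, dt);
      p.evt_slot = slot; p.evt_t = tnow + dt;
      push_event(i);
      return;
    }
    if (arm <= EPS) arm = EPS; // degenerate squeeze; resolves via tiny step
    p.dtype = DNSEG; p.dcenter = v; p.arm = arm;
    double dt = refl_sample_theta(unif_rand()) * arm * arm / D;
    p.evt_slot = std::min((int)(unif_rand() * d), d - 1);
    p.evt_t = tnow + dt;
    push_event(i);
  }

  void build_eseg(int i, double lo, double hi, double tnow) {
    Particle &p = P[i];
    p.dtype = DESEG; p.dedge = p.edge; p.dlo = lo; p.dhi = hi;
    int side; double dt;
    itv_exit_sample(hi - lo, p.x - lo, D, side, dt);
    p.evt_side = side; p.evt_t = tnow + dt;
    push_event(i);
  }

  void build_pair(int i, int j, double lo, double hi, double tnow) {
    if (P[i].x > P[j].x) std::swap(i, j);
    Particle &p1 = P[i], &p2 = P[j];
    double b = hi - lo;
    double X1 = p1.x - lo, X2 = p2.x - lo;
    double s2 = std::sqrt(2.0);
    double w0 = (X2 - X1) / s2, v0 = (X1 + X2) / s2;
    double slack = std::min(v0, s2 * b - v0) - w0; // > 0
    double wmax = w0 + 0.5 * std::min(w0, slack);
    double vlo = wmax, vhi = s2 * b - wmax;
    p1.dtype = DPAIR; p2.dtype = DPAIR;
    p1.dedge = p1.edge; p2.dedge = p2.edge;
    p1.dlo = lo; p1.dhi = hi; p2.dlo = lo; p2.dhi = hi;
    p1.partner = j; p2.partner = i;
    p1.pair_primary = true; p2.pair_primary = false;
    p1.w0 = w0; p1.wmax = wmax; p1.v0 = v0; p1.vlo = vlo; p1.vhi = vhi;
    p1.t0 = tnow;
    int sw, sv; double tw, tv;
    itv_exit_sample(wmax, w0, D, sw, tw);
    itv_exit_sample(vhi - vlo, v0 - vlo, D, sv, tv);
    if (tw <= tv) { p1.evt_coord = 0; p1.evt_side = sw; p1.evt_t = tnow + tw; }
    else { p1.evt_coord = 1; p1.evt_side = sv; p1.evt_t = tnow + tv; }
    P[j].version++; // invalidate any pending event of the secondary
    push_event(i);
  }

  // rebuild domains for all members of S (positions/times already current)
  void rebuild(std::vector<int> &S, double tnow) {
    std::vector<char> inS(P.size(), 0);
    for (size_t k = 0; k < S.size(); ++k)
      if (P[S[k]].status == 0) inS[S[k]] = 1;
    // clear member domains first
    for (size_t k = 0; k < S.size(); ++k) clear_domain(S[k]);
    std::vector<char> done(P.size(), 0);
    // pair candidates: members on the same edge
    if (interacting()) for (size_t a = 0; a < S.size(); ++a) {
      int i = S[a];
      if (done[i] || P[i].status != 0 || P[i].on_node) continue;
      for (size_t b2 = a + 1; b2 < S.size(); ++b2) {
        int j = S[b2];
        if (done[j] || P[j].status != 0 || P[j].on_node) continue;
        if (P[j].edge != P[i].edge) continue;
        int lo_i = (P[i].x <= P[j].x) ? i : j;
        int hi_i = (lo_i == i) ? j : i;
        // free bounds around the two of them, ignoring members
        double lo, hi;
        free_bounds(P[i].edge, 0.5 * (P[i].x + P[j].x), inS, lo, hi);
        // other members between or outside on the same edge?
        bool clean = true;
        for (size_t cth = 0; cth < S.size(); ++cth) {
          int q = S[cth];
          if (q == i || q == j || P[q].status != 0 || P[q].on_node) continue;
          if (P[q].edge == P[i].edge && P[q].x > lo && P[q].x < hi) clean = false;
        }
        if (!clean) continue;
        if (P[lo_i].x < lo || P[hi_i].x > hi) continue; // foreign domain between
        double gap = P[hi_i].x - P[lo_i].x;
        double wall = std::min(P[lo_i].x - lo, hi - P[hi_i].x);
        if (rule == 0 && gap < 1e-12 * net->elen[P[i].edge]) {
          // coincident: immediate encounter
          enc_time = tnow;
          P[i].status = 2; P[j].status = 2;
          done[i] = done[j] = 1;
          continue;
        }
        if (gap <= wall) {
          build_pair(lo_i, hi_i, lo, hi, tnow);
          done[i] = done[j] = 1;
        } else {
          double mid = 0.5 * (P[lo_i].x + P[hi_i].x);
          // temporarily mark to avoid double-constraint; build with explicit bounds
          build_eseg(lo_i, lo, mid, tnow);
          inS[lo_i] = 0; done[lo_i] = 1;
          build_eseg(hi_i, mid, hi, tnow);
          inS[hi_i] = 0; done[hi_i] = 1;
        }
        break;
      }
    }
    for (size_t a = 0; a < S.size(); ++a) {
      int i = S[a];
      if (done[i] || P[i].status != 0) continue;
      if (P[i].on_node) {
        build_node_domain(i, inS, tnow);
        inS[i] = 0; done[i] = 1;
      } else {
        double lo, hi;
        free_bounds(P[i].edge, P[i].x, inS, lo, hi);
        // constrain by other members on the same edge (half distance)
        if (interacting()) for (size_t b2 = 0; b2 < S.size(); ++b2) {
          int q = S[b2];
          if (q == i || P[q].status != 0 || !inS[q]) continue;
          if (!P[q].on_node && P[q].edge == P[i].edge) {
            double mid = 0.5 * (P[q].x + P[i].x);
            if (P[q].x < P[i].x) lo = std::max(lo, mid); else hi = std::min(hi, mid);
          } else if (P[q].on_node) {
            int e = P[i].edge;
            if (P[q].node == net->efrom[e])
              lo = std::max(lo, P[i].x / 2.0);
            else if (P[q].node == net->eto[e])
              hi = std::min(hi, (P[i].x + net->elen[e]) / 2.0);
          }
        }
        build_eseg(i, lo, hi, tnow);
        inS[i] = 0; done[i] = 1;
      }
    }
  }

  // no-passage propagate particle q (single domains only) to time tnow
  void sync_single(int q, double tnow) {
    Particle &p = P[q];
    double el = tnow - p.t;
    if (el < 0) el = 0;
    if (p.dtype == DNBHD) {
      const NbhdClass &c = (*classes)[net->nclass[p.dcenter]];
      int slot; double r;
      nbhd_nopass_sample(c, el, slot, r);
      int a = net->adj_ptr[p.dcenter] + slot;
      int e = net->adj_edge[a];
      if (r <= EPS) { p.on_node = true; p.node = p.dcenter; p.edge = -1; }
      else {
        p.on_node = false; p.edge = e;
        p.x = (net->efrom[e] == p.dcenter) ? r : net->elen[e] - r;
        p.node = -1;
      }
    } else if (p.dtype == DNSEG) {
      double r = refl_nopass_sample(p.arm, D, el);
      int d = net->deg[p.dcenter];
      int slot = std::min((int)(unif_rand() * d), d - 1);
      int a = net->adj_ptr[p.dcenter] + slot;
      int e = net->adj_edge[a];
      if (r <= EPS) { p.on_node = true; p.node = p.dcenter; p.edge = -1; }
      else {
        p.on_node = false; p.edge = e;
        p.x = (net->efrom[e] == p.dcenter) ? r : net->elen[e] - r;
        p.node = -1;
      }
    } else if (p.dtype == DESEG) {
      double l = p.dhi - p.dlo;
      double xx = itv_nopass_sample(l, p.x - p.dlo, D, el);
      p.x = p.dlo + xx;
    }
    p.t = tnow;
    clear_domain(q);
  }

  // no-passage propagate a PAIR (both members) to tnow
  void sync_pair(int i, double tnow) {
    int pr = P[i].pair_primary ? i : P[i].partner;
    int sc = P[pr].partner;
    Particle &p1 = P[pr];
    double el = tnow - p1.t0;
    if (el < 0) el = 0;
    double w = itv_nopass_sample(p1.wmax, p1.w0, D, el);
    double v = p1.vlo + itv_nopass_sample(p1.vhi - p1.vlo, p1.v0 - p1.vlo, D, el);
    double s2 = std::sqrt(2.0);
    double X1 = (v - w) / s2, X2 = (v + w) / s2;
    P[pr].x = p1.dlo + std::min(X1, X2);
    P[sc].x = P[pr].dlo + std::max(X1, X2);
    // identity of which particle is lower is exchangeable for equal D
    P[pr].t = tnow; P[sc].t = tnow;
    clear_domain(pr); clear_domain(sc);
  }

  // collect and sync all particles whose domain boundary contains the point
  // reached by the mover; returns the member set (mover included)
  void sync_touching(int mover, bool at_node, int v, int e, double x,
                     double tnow, std::vector<int> &S) {
    S.push_back(mover);
    if (!interacting()) return;
    for (size_t q = 0; q < P.size(); ++q) {
      if ((int)q == mover || P[q].status != 0 || P[q].dtype == DNONE) continue;
      const Particle &pq = P[q];
      bool touch = false;
      if (pq.dtype == DNBHD) {
        if (at_node) {
          for (int a = net->adj_ptr[pq.dcenter]; a < net->adj_ptr[pq.dcenter + 1]; ++a)
            if (net->adj_opp[a] == v) { touch = true; break; }
        }
      } else if (pq.dtype == DNSEG) {
        for (int a = net->adj_ptr[pq.dcenter]; a < net->adj_ptr[pq.dcenter + 1]; ++a) {
          int ee = net->adj_edge[a];
          double le = net->elen[ee];
          double bx = (net->efrom[ee] == pq.dcenter) ? pq.arm : le - pq.arm;
          if (at_node) {
            if (net->adj_opp[a] == v && std::fabs(pq.arm - le) < 1e-9 * le)
              { touch = true; break; }
          } else if (ee == e && std::fabs(bx - x) < 1e-9 * le) {
            touch = true; break;
          }
        }
      } else { // ESEG or PAIR
        int ee = pq.dedge;
        double le = net->elen[ee];
        if (at_node) {
          if ((net->efrom[ee] == v && pq.dlo < 1e-9 * le) ||
              (net->eto[ee] == v && pq.dhi > le * (1 - 1e-9))) touch = true;
        } else if (ee == e) {
          if (std::fabs(pq.dlo - x) < 1e-9 * le || std::fabs(pq.dhi - x) < 1e-9 * le)
            touch = true;
        }
      }
      if (touch) {
        if (pq.dtype == DPAIR) {
          int pr = pq.pair_primary ? (int)q : pq.partner;
          int sc = P[pr].partner;
          sync_pair((int)q, tnow);
          S.push_back(pr); S.push_back(sc);
        } else {
          sync_single((int)q, tnow);
          S.push_back((int)q);
        }
      }
    }
  }

  // main loop; returns when stop condition met
  void run(double tmax, long max_events) {
    while (!queue.empty()) {
      Ev ev = queue.top(); queue.pop();
      double tnow = std::get<0>(ev);
      int i = std::get<1>(ev);
      long ver = std::get<2>(ev);
      if (P[i].status != 0 || P[i].version != ver) continue;
      if (tnow > tmax) { return; }
      if (++n_events > max_events) return; // budget guard; caller inspects
      if (log_events) event_times.push_back(tnow);
      Particle &p = P[i];
      if (p.dtype == DPAIR) {
        // pair event (always owned by primary)
        int pr = i, sc = p.partner;
        double el = tnow - p.t0;
        double s2 = std::sqrt(2.0);
        double w, v;
        if (p.evt_coord == 0) {
          w = (p.evt_side == 0) ? 0.0 : p.wmax;
          v = p.vlo + itv_nopass_sample(p.vhi - p.vlo, p.v0 - p.vlo, D, el);
        } else {
          v = (p.evt_side == 0) ? p.vlo : p.vhi;
          w = itv_nopass_sample(p.wmax, p.w0, D, el);
        }
        double X1 = (v - w) / s2, X2 = (v + w) / s2;
        P[pr].x = p.dlo + std::min(X1, X2);
        P[sc].x = p.dlo + std::max(X1, X2);
        P[pr].t = tnow; P[sc].t = tnow;
        if (p.evt_coord == 0 && p.evt_side == 0) {
          // collision: encounter
          enc_time = tnow;
          if (rule == 0) { P[pr].status = 2; P[sc].status = 2; return; }
        }
        clear_domain(pr); clear_domain(sc);
        std::vector<int> S; S.push_back(pr); S.push_back(sc);
        rebuild(S, tnow);
        continue;
      }
      // single-particle exit
      bool at_node = false; int vnode = -1; int eedge = -1; double xpos = 0;
      if (p.dtype == DNBHD) {
        int a = net->adj_ptr[p.dcenter] + (p.evt_slot - 0);
        at_node = true; vnode = net->adj_opp[a];
        p.on_node = true; p.node = vnode;
        p.edge = -1;
      } else if (p.dtype == DNSEG) {
        int a = net->adj_ptr[p.dcenter] + p.evt_slot;
        int e = net->adj_edge[a];
        double le = net->elen[e];
        if (p.arm >= le * (1 - 1e-12)) {
          at_node = true; vnode = net->adj_opp[a];
          p.on_node = true; p.node = vnode; p.edge = -1;
        } else {
          at_node = false; eedge = e;
          xpos = (net->efrom[e] == p.dcenter) ? p.arm : le - p.arm;
          p.on_node = false; p.edge = e; p.x = xpos; p.node = -1;
        }
      } else { // ESEG
        int e = p.dedge;
        double le = net->elen[e];
        double xb = (p.evt_side == 0) ? p.dlo : p.dhi;
        if (xb < 1e-12 * le) {
          at_node = true; vnode = net->efrom[e];
          p.on_node = true; p.node = vnode; p.edge = -1;
        } else if (xb > le * (1 - 1e-12)) {
          at_node = true; vnode = net->eto[e];
          p.on_node = true; p.node = vnode; p.edge = -1;
        } else {
          at_node = false; eedge = e; xpos = xb;
          p.x = xb;
        }
      }
      p.t = tnow;
      clear_domain(i);
      if (at_node && rule == 1 && net->is_target[vnode]) {
        p.status = 1;
        p.evt_t = tnow; // records absorption time
        // sync touching neighbors so their domains stay valid
        std::vector<int> S;
        sync_touching(i, at_node, vnode, eedge, xpos, tnow, S);
        S.erase(S.begin()); // mover absorbed; rebuild the rest
        if (!S.empty()) rebuild(S, tnow);
        // all absorbed?
        bool any_free = false;
        for (size_t q = 0; q < P.size(); ++q) if (P[q].status == 0) any_free = true;
        if (!any_free) return;
        continue;
      }
      std::vector<int> S;
      sync_touching(i, at_node, vnode, eedge, xpos, tnow, S);
      rebuild(S, tnow);
      if (rule == 0 && enc_time >= 0) return; // coincidence at rebuild
    }
  }
};

const double Engine::EPS = 1e-11;

static Net make_net(List net) {
  Net N;
  IntegerVector deg = net["deg"], adj_ptr = net["adj_ptr"],
    adj_edge = net["adj_edge"], adj_opp = net["adj_opp"],
    efrom = net["edge_from"], eto = net["edge_to"], ncl = net["node_class"];
  NumericVector elen = net["edge_len"];
  LogicalVector tgt = net["is_target"];
  N.n = deg.size(); N.E = elen.size();
  N.deg.assign(deg.begin(), deg.end());
  N.adj_ptr.assign(adj_ptr.begin(), adj_ptr.end());
  N.adj_edge.assign(adj_edge.begin(), adj_edge.end());
  N.adj_opp.assign(adj_opp.begin(), adj_opp.end());
  N.efrom.assign(efrom.begin(), efrom.end());
  N.eto.assign(eto.begin(), eto.end());
  N.elen.assign(elen.begin(), elen.end());
  N.nclass.assign(ncl.begin(), ncl.end());
  N.is_target.resize(N.n);
  for (int i = 0; i < N.n; ++i) N.is_target[i] = tgt[i] ? 1 : 0;
  return N;
}

static std::vector<NbhdClass> make_classes(List classes, double D) {
  std::vector<NbhdClass> out;
  for (int i = 0; i < classes.size(); ++i)
    out.push_back(make_class(classes[i], D));
  return out;
}

// Run one simulation with the given particles.
// starts: matrix with columns (on_node, node, edge, x) 0-based indices
// rule: 0 = stop at first pair encounter, 1 = absorb at target nodes
// [[Rcpp::export]]
List cpp_run_multi(List net, List classes, double D, NumericMatrix starts,
                   int rule, double tmax, double max_events) {
  Net N = make_net(net);
  std::vector<NbhdClass> C = make_classes(classes, D);
  Engine eng;
  eng.net = &N; eng.classes = &C; eng.D = D; eng.rule = rule;
  eng.log_events = true;
  int np = starts.nrow();
  eng.P.resize(np);
  for (int i = 0; i < np; ++i) {
    Particle &p = eng.P[i];
    p.on_node = starts(i, 0) > 0.5;
    p.node = (int)starts(i, 1);
    p.edge = (int)starts(i, 2);
    p.x = starts(i, 3);
    p.t = 0;
  }
  std::vector<int> S;
  for (int i = 0; i < np; ++i) S.push_back(i);
  eng.rebuild(S, 0.0);
  if (!(eng.rule == 0 && eng.enc_time >= 0))
    eng.run(tmax, (long)max_events);
  NumericVector abst(np, NA_REAL);
  IntegerVector status(np);
  NumericVector fx(np), ft(np);
  IntegerVector fedge(np), fnode(np);
  for (int i = 0; i < np; ++i) {
    status[i] = eng.P[i].status;
    if (eng.P[i].status == 1) abst[i] = eng.P[i].evt_t;
    ft[i] = eng.P[i].t;
    fedge[i] = eng.P[i].on_node ? -1 : eng.P[i].edge;
    fnode[i] = eng.P[i].on_node ? eng.P[i].node : -1;
    fx[i] = eng.P[i].x;
  }
  return List::create(_["status"] = status,
                      _["absorption_time"] = abst,
                      _["encounter_time"] = eng.enc_time < 0 ? NA_REAL : eng.enc_time,
                      _["t"] = ft, _["edge"] = fedge, _["node"] = fnode,
                      _["x"] = fx, _["n_events"] = (double)eng.n_events,
                      _["event_times"] = wrap(eng.event_times));
}

// batch of independent pair-encounter simulations; starts has 4 columns
// (edge1, x1, edge2, x2), 0-based edges
// [[Rcpp::export]]
NumericVector cpp_pair_encounter_batch(List net, List classes, double D,
                                       NumericMatrix starts, double tmax,
                                       double max_events) {
  Net N = make_net(net);
  std::vector<NbhdClass> C = make_classes(classes, D);
  int n = starts.nrow();
  NumericVector out(n, NA_REAL);
  for (int r = 0; r < n; ++r) {
    Engine eng;
    eng.net = &N; eng.classes = &C; eng.D = D; eng.rule = 0;
    eng.P.resize(2);
    for (int i = 0; i < 2; ++i) {
      Particle &p = eng.P[i];
      p.on_node = false;
      p.edge = (int)starts(r, 2 * i);
      p.x = starts(r, 2 * i + 1);
      p.node = -1; p.t = 0;
    }
    if (eng.P[0].edge == eng.P[1].edge &&
        std::fabs(eng.P[0].x - eng.P[1].x) < 1e-12) {
      out[r] = 0.0;
      continue;
    }
    std::vector<int> S; S.push_back(0); S.push_back(1);
    eng.rebuild(S, 0.0);
    if (eng.enc_time < 0) eng.run(tmax, (long)max_events);
    if (eng.enc_time >= 0) out[r] = eng.enc_time;
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// fast batch of single-particle first-passage times from a fixed start to
// the flagged target nodes; start may be a node or an (edge, x) position
// [[Rcpp::export]]
NumericVector cpp_fpt_batch(List net, List classes, double D,
                            bool start_on_node, int start_node, int start_edge,
                            double start_x, int n, double tmax) {
  Net N = make_net(net);
  std::vector<NbhdClass> C = make_classes(classes, D);
  NumericVector out(n, NA_REAL);
  for (int r = 0; r < n; ++r) {
    double t = 0;
    int v;
    if (start_on_node) v = start_node;
    else {
      int side; double dt;
      itv_exit_sample(N.elen[start_edge], start_x, D, side, dt);
      t += dt;
      v = (side == 0) ? N.efrom[start_edge] : N.eto[start_edge];
    }
    while (!N.is_target[v] && t <= tmax) {
      const NbhdClass &c = C[N.nclass[v]];
      int slot; double dt;
      nbhd_exit_sample(c, slot, dt);
      t += dt;
      v = N.adj_opp[N.adj_ptr[v] + slot];
    }
    if (N.is_target[v] && t <= tmax) out[r] = t;
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
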