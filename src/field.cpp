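#include <Rcpp.h>
using namespace Rcpp;

// reduce x to [0, 2*pi)
static inline double mod_2pi(double x) {
  x -= 2.0 * M_PI * std::floor(x / (2.0 * M_PI));
  if (x >= 2.0 * M_PI) x = 0.0;
  return x;
}

// Geodesic distance on a cone parameterized by its unroll factor c in (0, 1]:
// the ratio of the unrolled-sector angle to 2*pi (equals the sine of the cone
// half-angle; c = 1 is a flat disc).  Points are (slant radius, azimuth).
// Unrolling maps an azimuth difference dth (wrapped to [0, pi]) to an angle
// alpha = c * dth; the geodesic is the planar chord, or passes the apex
// (length ra + rb) when alpha >= pi.
static inline double cone_d2(double ra, double ta, double rb, double tb,
                             double c) {
  double dth = mod_2pi(std::fabs(ta - tb));
  if (dth > M_PI) dth = 2.0 * M_PI - dth;
  double al = c * dth;
  if (al >= M_PI) {
    double s = ra + rb;
    return s * s;
  }
  double d2 = ra * ra + rb * rb - 2.0 * ra * rb * std::cos(al);
  return d2 > 0.0 ? d2 : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_cone_distance(NumericVector rho_a, NumericVector th_a,
                                NumericVector rho_b, NumericVector th_b,
                                double unroll) {
  R_xlen_t n = rho_a.size();
  if (th_a.size() != n || rho_b.size() != n || th_b.size() != n)
    stop("coordinate vectors must have equal length");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (rho_a[i] < 0.0 || rho_b[i] < 0.0)
      stop("slant radii must be non-negative");
    out[i] = std::sqrt(cone_d2(rho_a[i], th_a[i], rho_b[i], th_b[i], unroll));
  }
  return out;
}

// Total inhibition sensed at a probe point on the competent circle.
// Primary field: sum over primordia of (d0/d)^s.  Optional secondary field
// of class (ii): sources are primordia of age >= tau, kernel (d1/d)^s,
// combined either redundantly (E1 + beta*E2, mode 1) or synergetically
// (E1*E2, mode 2).  mode 0 is the primary field alone.
struct CircleField {
  const double *pth, *ptb, *pr0;
  int n;
  double t, V0, Rc, c, d0, s;
  int kform;  // 0 = power law (d0/d)^s, 1 = exponential exp(s*(1 - d/d0))
  int mode;
  double d1, tau, beta;
  double rcut;  // sources with slant radius beyond this are pruned
  bool s_is_2;
  // during circle scans a probe exactly on a source has infinite
  // inhibition; only direct field evaluation treats it as an error
  bool singular_error;

  // single-source kernel at squared distance d2 for a field of range dr
  inline double kval(double d2, double dr) const {
    if (kform == 1) return std::exp(s * (1.0 - std::sqrt(d2) / dr));
    double q = (dr * dr) / d2;
    return s_is_2 ? q : std::pow(q, 0.5 * s);
  }

  double operator()(double theta) const {
    double E1 = 0.0, E2 = 0.0;
    for (int k = 0; k < n; ++k) {
      double rb = pr0[k] + V0 * (t - ptb[k]);
      if (rb > rcut) continue;
      double d2 = cone_d2(Rc, theta, rb, pth[k], c);
      if (d2 <= 0.0) {
        if (singular_error)
          stop("probe coincides with an existing primordium (singular distance)");
        return R_PosInf;
      }
      E1 += kval(d2, d0);
      if (mode != 0 && (t - ptb[k]) >= tau) E2 += kval(d2, d1);
    }
    if (mode == 1) return E1 + beta * E2;
    if (mode == 2) return E1 * E2;
    return E1;
  }

  // Evaluate the combined field on n_grid equispaced azimuths.  Source-major
  // accumulation: for each source the cosine of the unrolled angle along the
  // grid advances by a fixed rotation, so only O(1) trig calls per source
  // are needed.  The grid is covered in two passes around each source (the
  // wrapped azimuth difference increasing up to pi on either side).
  void scan(int n_grid, std::vector<double> &out) const {
    double stepg = 2.0 * M_PI / n_grid;
    std::vector<double> E1(n_grid, 0.0), E2;
    bool use2 = mode != 0;
    if (use2) E2.assign(n_grid, 0.0);
    double cs = std::cos(c * stepg), sn = std::sin(c * stepg);
    for (int k = 0; k < n; ++k) {
      double rb = pr0[k] + V0 * (t - ptb[k]);
      if (rb > rcut) continue;
      bool old2 = use2 && (t - ptb[k]) >= tau;
      double A = Rc * Rc + rb * rb, B = 2.0 * Rc * rb;
      int i0 = (int)std::ceil(pth[k] / stepg);
      double del0 = i0 * stepg - pth[k];  // in [0, stepg)
      // upward pass: wrapped difference del0 + j*stepg while <= pi
      double ca = std::cos(c * del0), sa = std::sin(c * del0);
      for (int j = 0; del0 + j * stepg <= M_PI; ++j) {
        int ii = (i0 + j) % n_grid;
        double d2 = A - B * ca;
        if (d2 <= 0.0) {
          E1[ii] = R_PosInf;
        } else {
          E1[ii] += kval(d2, d0);
          if (old2) E2[ii] += kval(d2, d1);
        }
        double nca = ca * cs - sa * sn;
        sa = ca * sn + sa * cs;
        ca = nca;
      }
      // downward pass: wrapped difference (stepg - del0) + j*stepg while < pi
      double del0d = stepg - del0;  // in (0, stepg]
      ca = std::cos(c * del0d);
      sa = std::sin(c * del0d);
      for (int j = 0; del0d + j * stepg < M_PI; ++j) {
        int ii = (i0 - 1 - j) % n_grid;
        if (ii < 0) ii += n_grid;
        double d2 = A - B * ca;
        if (d2 <= 0.0) {
          E1[ii] = R_PosInf;
        } else {
          E1[ii] += kval(d2, d0);
          if (old2) E2[ii] += kval(d2, d1);
        }
        double nca = ca * cs - sa * sn;
        sa = ca * sn + sa * cs;
        ca = nca;
      }
    }
    out.resize(n_grid);
    for (int i = 0; i < n_grid; ++i) {
      if (mode == 1) out[i] = E1[i] + beta * E2[i];
      else if (mode == 2) out[i] = E1[i] * E2[i];
      else out[i] = E1[i];
    }
  }
};

static CircleField make_field(double t, const NumericVector &p_azimuth,
                              const NumericVector &p_birth,
                              const NumericVector &p_r0, double V0, double Rc,
                              double unroll, double d0, double s, int kform,
                              int mode, double d1, double tau, double beta,
                              double prune_eps, bool singular_error) {
  CircleField F;
  F.singular_error = singular_error;
  F.kform = kform;
  F.pth = p_azimuth.begin();
  F.ptb = p_birth.begin();
  F.pr0 = p_r0.begin();
  F.n = p_azimuth.size();
  F.t = t;
  F.V0 = V0;
  F.Rc = Rc;
  F.c = unroll;
  F.d0 = d0;
  F.s = s;
  F.mode = mode;
  F.d1 = d1;
  F.tau = tau;
  F.beta = beta;
  F.s_is_2 = std::fabs(s - 2.0) < 1e-12;
  // A source's kernel on the circle is maximal at distance |rb - Rc|;
  // beyond rcut its contribution is below prune_eps everywhere.
  double dref = (mode != 0 && d1 > d0) ? d1 : d0;
  if (prune_eps <= 0.0) F.rcut = R_PosInf;
  else if (kform == 1)
    F.rcut = Rc + dref * (1.0 - std::log(prune_eps) / s);
  else
    F.rcut = Rc + dref * std::pow(prune_eps, -1.0 / s);
  return F;
}

// [[Rcpp::export]]
NumericVector cpp_field_on_circle(NumericVector theta, double t,
                                  NumericVector p_azimuth,
                                  NumericVector p_birth, NumericVector p_r0,
                                  double V0, double Rc, double unroll,
                                  double d0, double s, int kform, int mode,
                                  double d1, double tau, double beta,
                                  double prune_eps) {
  CircleField F = make_field(t, p_azimuth, p_birth, p_r0, V0, Rc, unroll, d0,
                             s, kform, mode, d1, tau, beta, prune_eps, true);
  R_xlen_t m = theta.size();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) out[i] = F(theta[i]);
  return out;
}

// Golden-section minimization of the field over [a, b] to tolerance tol.
static double golden_min(const CircleField &F, double a, double b, double tol,
                         double &xmin) {
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = F(x1), f2 = F(x2);
  while (b - a > tol) {
    if (f1 < f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a); f1 = F(x1);
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a); f2 = F(x2);
    }
  }
  xmin = 0.5 * (a + b);
  return F(xmin);
}

static inline double wrap_2pi(double x) { return mod_2pi(x); }

// Global minimum of the inhibition on the competent circle: coarse scan on
// n_grid equispaced azimuths isolates the basin, golden-section refines the
// minimizer to eps_theta.
// [[Rcpp::export]]
List cpp_min_on_circle(double t, NumericVector p_azimuth,
                       NumericVector p_birth, NumericVector p_r0, double V0,
                       double Rc, double unroll, double d0, double s,
                       int kform, int mode, double d1, double tau, double beta,
                       double prune_eps, int n_grid, double eps_theta) {
  if (p_azimuth.size() == 0)
    stop("cannot minimize inhibition with no primordia (degenerate state)");
  CircleField F = make_field(t, p_azimuth, p_birth, p_r0, V0, Rc, unroll, d0,
                             s, kform, mode, d1, tau, beta, prune_eps, false);
  double step = 2.0 * M_PI / n_grid;
  std::vector<double> vals;
  F.scan(n_grid, vals);
  double best = R_PosInf;
  int ibest = 0;
  for (int i = 0; i < n_grid; ++i) {
    if (vals[i] < best) { best = vals[i]; ibest = i; }
  }
  double lo = (ibest - 1) * step, hi = (ibest + 1) * step;
  double xmin;
  double Emin = golden_min(F, lo, hi, eps_theta, xmin);
  return List::create(_["theta"] = wrap_2pi(xmin), _["E"] = Emin);
}

// All refined local minima of the field whose value is <= threshold and
// whose azimuth is farther than min_sep (circular) from every azimuth in
// `exclude`.  Used to detect additional concomitant initia after one has
// been placed.  Returned sorted by increasing field value.
// [[Rcpp::export]]
List cpp_minima_below(double t, NumericVector p_azimuth, NumericVector p_birth,
                      NumericVector p_r0, double V0, double Rc, double unroll,
                      double d0, double s, int kform, int mode, double d1,
                      double tau, double beta, double prune_eps, int n_grid,
                      double eps_theta, double threshold, double min_sep,
                      NumericVector exclude) {
  CircleField F = make_field(t, p_azimuth, p_birth, p_r0, V0, Rc, unroll, d0,
                             s, kform, mode, d1, tau, beta, prune_eps, false);
  double step = 2.0 * M_PI / n_grid;
  std::vector<double> vals;
  F.scan(n_grid, vals);
  std::vector<double> mth, mE;
  for (int i = 0; i < n_grid; ++i) {
    double prev = vals[(i + n_grid - 1) % n_grid];
    double next = vals[(i + 1) % n_grid];
    if (vals[i] <= prev && vals[i] <= next) {
      double xmin;
      double Emin = golden_min(F, (i - 1) * step, (i + 1) * step, eps_theta,
                               xmin);
      if (Emin > threshold) continue;
      xmin = wrap_2pi(xmin);
      bool near = false;
      for (R_xlen_t j = 0; j < exclude.size() && !near; ++j) {
        double dth = mod_2pi(std::fabs(xmin - exclude[j]));
        if (dth > M_PI) dth = 2.0 * M_PI - dth;
        if (dth <= min_sep) near = true;
      }
      for (size_t j = 0; j < mth.size() && !near; ++j) {
        double dth = mod_2pi(std::fabs(xmin - mth[j]));
        if (dth > M_PI) dth = 2.0 * M_PI - dth;
        if (dth <= min_sep) near = true;
      }
      if (!near) { mth.push_back(xmin); mE.push_back(Emin); }
    }
  }
  // sort by field value
  std::vector<size_t> ord(mth.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return mE[a] < mE[b]; });
  NumericVector oth(ord.size()), oE(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    oth[i] = mth[ord[i]];
    oE[i] = mE[ord[i]];
  }
  return List::create(_["theta"] = oth, _["E"] = oE);
}
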