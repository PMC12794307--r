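// Fixed-step off-lattice spin random walk inside impermeable geometries,
// with accumulation of the time-integrated positions over the two PGSE
// gradient lobes (sufficient statistics for rectangular-pulse phase
// accrual). Geometries: free space, sphere, infinite cylinder (z axis),
// finite cylinder with reflecting caps (z axis), and a union of spheres
// and finite cylinders in arbitrary pose (parametric glia).
//
// Boundary rule: specular reflection of the residual step off the crossed
// surface; at junctions of a union where the reflected residual would
// still exit, the step is rejected (walker stays), keeping walkers inside
// at all times. Uses R's RNG, so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// ---- primitive containment -------------------------------------------

static inline bool in_sphere(const double* p, double R) {
  return p[0] * p[0] + p[1] * p[1] + p[2] * p[2] <= R * R;
}
static inline bool in_icyl(const double* p, double R) {
  return p[0] * p[0] + p[1] * p[1] <= R * R;
}
static inline bool in_fcyl(const double* p, double R, double H) {
  return std::fabs(p[2]) <= H && p[0] * p[0] + p[1] * p[1] <= R * R;
}

// union primitive row: {type(0 sphere,1 fincyl), cx,cy,cz, R, H, ax,ay,az}
static inline bool in_prim(const double* p, const double* row) {
  double q[3] = {p[0] - row[1], p[1] - row[2], p[2] - row[3]};
  if (row[0] < 0.5) {
    return dot3(q, q) <= row[4] * row[4];
  }
  const double* a = row + 6;
  double t = dot3(q, a);
  if (std::fabs(t) > row[5]) return false;
  double r2 = dot3(q, q) - t * t;
  return r2 <= row[4] * row[4];
}

static bool in_union(const double* p, const NumericMatrix& prims) {
  for (int k = 0; k < prims.nrow(); ++k)
    if (in_prim(p, &prims(k, 0))) return true;
  return false;
}

struct Geometry {
  int type;                 // 0 free, 1 sphere, 2 icyl, 3 fcyl, 4 union
  double R, H;
  const NumericMatrix* prims;
  // prims rows stored column-major by Rcpp; copy into a flat buffer for
  // row-contiguous access
  std::vector<double> pbuf;
  int np;

  bool inside(const double* p) const {
    switch (type) {
    case 0: return true;
    case 1: return in_sphere(p, R);
    case 2: return in_icyl(p, R);
    case 3: return in_fcyl(p, R, H);
    default:
      for (int k = 0; k < np; ++k)
        if (in_prim(p, &pbuf[9 * k])) return true;
      return false;
    }
  }
};

// outward surface normal of a primitive at (or near) point p
static void prim_normal(const double* p, const double* row, double* n) {
  double q[3] = {p[0] - row[1], p[1] - row[2], p[2] - row[3]};
  if (row[0] < 0.5) {  // sphere
    double nn = std::sqrt(dot3(q, q));
    if (nn < 1e-12) { n[0] = 0; n[1] = 0; n[2] = 1; return; }
    n[0] = q[0] / nn; n[1] = q[1] / nn; n[2] = q[2] / nn;
    return;
  }
  const double* a = row + 6;
  double t = dot3(q, a);
  double rad[3] = {q[0] - t * a[0], q[1] - t * a[1], q[2] - t * a[2]};
  double rr = std::sqrt(dot3(rad, rad));
  // closer to a cap or to the lateral surface?
  double dcap = row[5] - std::fabs(t);
  double dlat = row[4] - rr;
  if (dcap < dlat) {
    double s = (t >= 0) ? 1.0 : -1.0;
    n[0] = s * a[0]; n[1] = s * a[1]; n[2] = s * a[2];
  } else {
    if (rr < 1e-12) { n[0] = 0; n[1] = 0; n[2] = 1; return; }
    n[0] = rad[0] / rr; n[1] = rad[1] / rr; n[2] = rad[2] / rr;
  }
}

// distance from p to the surface of a primitive (positive inside)
static double prim_depth(const double* p, const double* row) {
  double q[3] = {p[0] - row[1], p[1] - row[2], p[2] - row[3]};
  if (row[0] < 0.5) return row[4] - std::sqrt(dot3(q, q));
  const double* a = row + 6;
  double t = dot3(q, a);
  double rad2 = dot3(q, q) - t * t;
  double dlat = row[4] - std::sqrt(std::max(rad2, 0.0));
  double dcap = row[5] - std::fabs(t);
  return std::min(dlat, dcap);
}

// Take one fixed-length step from p along u inside the geometry.
// Returns the end position in p (modified in place).
static void take_step(double* p, const double* u, double L,
                      const Geometry& geom) {
  if (geom.type == 0) {
    p[0] += L * u[0]; p[1] += L * u[1]; p[2] += L * u[2];
    return;
  }
  double dir[3] = {u[0], u[1], u[2]};
  double pos[3] = {p[0], p[1], p[2]};
  double rem = L;
  for (int iter = 0; iter < 6; ++iter) {
    double cand[3] = {pos[0] + rem * dir[0], pos[1] + rem * dir[1],
                      pos[2] + rem * dir[2]};
    if (geom.inside(cand)) {
      p[0] = cand[0]; p[1] = cand[1]; p[2] = cand[2];
      return;
    }
    // bisect to the boundary along the remaining step
    double lo = 0.0, hi = 1.0;
    for (int b = 0; b < 40; ++b) {
      double mid = 0.5 * (lo + hi);
      double pm[3] = {pos[0] + mid * rem * dir[0],
                      pos[1] + mid * rem * dir[1],
                      pos[2] + mid * rem * dir[2]};
      if (geom.inside(pm)) lo = mid; else hi = mid;
    }
    double xc[3] = {pos[0] + lo * rem * dir[0], pos[1] + lo * rem * dir[1],
                    pos[2] + lo * rem * dir[2]};   // just inside
    // surface normal at the crossing
    double n[3] = {0, 0, 1};
    switch (geom.type) {
    case 1: {
      double nn = std::sqrt(dot3(xc, xc));
      if (nn > 1e-12) { n[0] = xc[0]/nn; n[1] = xc[1]/nn; n[2] = xc[2]/nn; }
      break;
    }
    case 2: {
      double rr = std::sqrt(xc[0]*xc[0] + xc[1]*xc[1]);
      if (rr > 1e-12) { n[0] = xc[0]/rr; n[1] = xc[1]/rr; n[2] = 0; }
      break;
    }
    case 3: {
      double row[9] = {1, 0, 0, 0, geom.R, geom.H, 0, 0, 1};
      prim_normal(xc, row, n);
      break;
    }
    default: {
      // normal of the containing primitive whose surface is nearest
      double best = 1e300; int kbest = -1;
      for (int k = 0; k < geom.np; ++k) {
        const double* row = &geom.pbuf[9 * k];
        if (!in_prim(xc, row)) continue;
        double d = prim_depth(xc, row);
        if (d < best) { best = d; kbest = k; }
      }
      if (kbest >= 0) prim_normal(xc, &geom.pbuf[9 * kbest], n);
      break;
    }
    }
    double un = dot3(dir, n);
    dir[0] -= 2 * un * n[0]; dir[1] -= 2 * un * n[1]; dir[2] -= 2 * un * n[2];
    rem *= (1.0 - lo);
    pos[0] = xc[0]; pos[1] = xc[1]; pos[2] = xc[2];
    if (rem < 1e-10 * L) break;
  }
  // unresolved after several reflections (junction / corner): reject the
  // step so the walker never leaves the compartment
  if (geom.inside(pos)) { p[0] = pos[0]; p[1] = pos[1]; p[2] = pos[2]; }
}

// [[Rcpp::export]]
List mc_walk_cpp(NumericMatrix pos0, int geom_type, double R, double H,
                 NumericMatrix prims, double step, int n_steps,
                 int n_delta, int i_Delta, int record_every) {
  int n = pos0.nrow();
  Geometry geom;
  geom.type = geom_type; geom.R = R; geom.H = H; geom.np = prims.nrow();
  geom.prims = &prims;
  if (geom_type == 4) {
    geom.pbuf.resize(9 * geom.np);
    for (int k = 0; k < geom.np; ++k)
      for (int j = 0; j < 9; ++j) geom.pbuf[9 * k + j] = prims(k, j);
  }

  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i) {
    P[3 * i] = pos0(i, 0); P[3 * i + 1] = pos0(i, 1); P[3 * i + 2] = pos0(i, 2);
  }

  NumericMatrix X1(n, 3), X2(n, 3);
  int n_rec = (record_every > 0) ? (n_steps / record_every + 1) : 0;
  NumericVector traj(record_every > 0 ? (R_xlen_t)n_rec * n * 3 : 0);
  int rec_i = 0;
  if (record_every > 0) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        traj[(R_xlen_t)rec_i + n_rec * ((R_xlen_t)i + (R_xlen_t)n * d)] =
          P[3 * i + d];
    rec_i = 1;
  }

  RNGScope scope;
  for (int t = 1; t <= n_steps; ++t) {
    bool lobe1 = (t <= n_delta);
    bool lobe2 = (t > i_Delta && t <= i_Delta + n_delta);
    for (int i = 0; i < n; ++i) {
      double u[3];
      double nn = 0.0;
      do {
        u[0] = norm_rand(); u[1] = norm_rand(); u[2] = norm_rand();
        nn = std::sqrt(dot3(u, u));
      } while (nn < 1e-8);
      u[0] /= nn; u[1] /= nn; u[2] /= nn;
      take_step(&P[3 * i], u, step, geom);
      if (lobe1) {
        X1(i, 0) += P[3 * i]; X1(i, 1) += P[3 * i + 1]; X1(i, 2) += P[3 * i + 2];
      } else if (lobe2) {
        X2(i, 0) += P[3 * i]; X2(i, 1) += P[3 * i + 1]; X2(i, 2) += P[3 * i + 2];
      }
    }
    if (record_every > 0 && t % record_every == 0) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          traj[(R_xlen_t)rec_i + n_rec * ((R_xlen_t)i + (R_xlen_t)n * d)] =
            P[3 * i + d];
      ++rec_i;
    }
  }

  NumericMatrix pos(n, 3);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = P[3 * i]; pos(i, 1) = P[3 * i + 1]; pos(i, 2) = P[3 * i + 2];
  }
  List out = List::create(Named("positions") = pos,
                          Named("X1") = X1, Named("X2") = X2);
  if (record_every > 0) {
    traj.attr("dim") = IntegerVector::create(n_rec, n, 3);
    out["trajectory"] = traj;
  }
  return out;
}
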