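// Douglas-Gunn time-split finite-difference solver for the Pennes bioheat
// equation in temperature-increase form:
//   rho c dT/dt = div(lambda grad T) - LB(T) hb0 T + (1.1^T - 1) Pmet0 + Pem
// Diffusion is treated implicitly per direction (three tridiagonal solves
// per step); the nonlinear perfusion/metabolic terms are lagged one step.
// Heterogeneous conductivity uses harmonic-mean face conductances; the
// Robin condition lambda dT/dn = -h T is applied on tissue-air faces
// through a half-cell series resistance.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  R_xlen_t N;
  double dx;
};

// face conductance divided by rho*c*dx^2 between active cells i and j
inline double faceCoef(const double* lam, const double* irc, R_xlen_t i,
                       R_xlen_t j, double dx) {
  double li = lam[i], lj = lam[j];
  if (li <= 0.0 || lj <= 0.0) return 0.0;
  double kf = 2.0 * li * lj / (li + lj);
  return kf * irc[i] / (dx * dx);
}

// Robin sink per exposed face, divided by rho*c: (1/dx) / (1/h + dx/(2 lam))
inline double robinCoef(const double* lam, const double* irc, R_xlen_t i,
                        double dx, double hAmb) {
  if (hAmb <= 0.0) return 0.0;
  double res = 1.0 / hAmb + dx / (2.0 * lam[i]);
  return irc[i] / (dx * res);
}

}  // namespace

// Precompute per-direction explicit coefficients (gm, gp, rob) and Thomas
// factors (w, invd) for M_d = I - (dt/2) D_d. Lines run along direction d;
// inactive cells are identity rows.
static void precomputeDirection(const Grid& g, int dir, const double* lam,
                                const double* irc, const int* act,
                                double hAmb, bool robinAtBounds, double dt,
                                std::vector<double>& gm, std::vector<double>& gp,
                                std::vector<double>& rob,
                                std::vector<double>& w,
                                std::vector<double>& invd) {
  const R_xlen_t N = g.N;
  gm.assign(N, 0.0); gp.assign(N, 0.0); rob.assign(N, 0.0);
  w.assign(N, 0.0); invd.assign(N, 0.0);
  R_xlen_t stride = (dir == 0) ? 1 : (dir == 1 ? (R_xlen_t)g.nx
                                               : (R_xlen_t)g.nx * g.ny);
  int len = (dir == 0) ? g.nx : (dir == 1 ? g.ny : g.nz);

  for (R_xlen_t i = 0; i < N; ++i) {
    if (!act[i]) continue;
    int pos;
    if (dir == 0) pos = (int)(i % g.nx);
    else if (dir == 1) pos = (int)((i / g.nx) % g.ny);
    else pos = (int)(i / ((R_xlen_t)g.nx * g.ny));
    // minus-side face
    if (pos > 0 && act[i - stride]) {
      gm[i] = faceCoef(lam, irc, i, i - stride, g.dx);
    } else if (pos > 0 || robinAtBounds) {
      if (pos == 0 || !act[i - stride]) rob[i] += robinCoef(lam, irc, i, g.dx, hAmb);
    }
    // plus-side face
    if (pos < len - 1 && act[i + stride]) {
      gp[i] = faceCoef(lam, irc, i, i + stride, g.dx);
    } else if (pos < len - 1 || robinAtBounds) {
      if (pos == len - 1 || !act[i + stride]) rob[i] += robinCoef(lam, irc, i, g.dx, hAmb);
    }
  }

  // Thomas factorization per line
  const double h = dt / 2.0;
  R_xlen_t nLines = N / len;
  for (R_xlen_t line = 0; line < nLines; ++line) {
    // first index of this line
    R_xlen_t base;
    if (dir == 0) base = line * g.nx;
    else if (dir == 1) base = (line % g.nx) + (line / g.nx) * (R_xlen_t)g.nx * g.ny;
    else base = line;
    double wPrev = 0.0;
    for (int k = 0; k < len; ++k) {
      R_xlen_t i = base + (R_xlen_t)k * stride;
      double sub, dia, sup;
      if (act[i]) {
        sub = -h * gm[i];
        dia = 1.0 + h * (gm[i] + gp[i] + rob[i]);
        sup = -h * gp[i];
      } else { sub = 0.0; dia = 1.0; sup = 0.0; }
      double denom = dia - sub * wPrev;
      invd[i] = 1.0 / denom;
      wPrev = sup * invd[i];
      w[i] = wPrev;
    }
  }
}

// In-place tridiagonal solve along direction using precomputed factors.
// Sweeps are organised plane-by-plane with unit-stride inner loops so the
// y and z solves stay cache-friendly on large grids.
static void thomasSolve(const Grid& g, int dir, const std::vector<double>& gm,
                        const std::vector<double>& w,
                        const std::vector<double>& invd, double dt,
                        const int* act, std::vector<double>& r) {
  const double h = dt / 2.0;
  const R_xlen_t sy = g.nx, sz = (R_xlen_t)g.nx * g.ny;
  if (dir == 0) {
    R_xlen_t nLines = g.N / g.nx;
    for (R_xlen_t line = 0; line < nLines; ++line) {
      R_xlen_t base = line * g.nx;
      double yPrev = 0.0;
      for (int k = 0; k < g.nx; ++k) {
        R_xlen_t i = base + k;
        double sub = act[i] ? -h * gm[i] : 0.0;
        yPrev = (r[i] - sub * yPrev) * invd[i];
        r[i] = yPrev;
      }
      for (int k = g.nx - 2; k >= 0; --k) {
        R_xlen_t i = base + k;
        r[i] -= w[i] * r[i + 1];
      }
    }
  } else if (dir == 1) {
    for (int z = 0; z < g.nz; ++z) {
      R_xlen_t pb = (R_xlen_t)z * sz;
      // forward: first y-row as-is, then rows referencing the previous row
      for (int x = 0; x < g.nx; ++x) {
        R_xlen_t i = pb + x;
        r[i] *= invd[i];
      }
      for (int y = 1; y < g.ny; ++y) {
        R_xlen_t rb = pb + (R_xlen_t)y * sy;
        for (int x = 0; x < g.nx; ++x) {
          R_xlen_t i = rb + x;
          double sub = act[i] ? -h * gm[i] : 0.0;
          r[i] = (r[i] - sub * r[i - sy]) * invd[i];
        }
      }
      for (int y = g.ny - 2; y >= 0; --y) {
        R_xlen_t rb = pb + (R_xlen_t)y * sy;
        for (int x = 0; x < g.nx; ++x) {
          R_xlen_t i = rb + x;
          r[i] -= w[i] * r[i + sy];
        }
      }
    }
  } else {
    for (R_xlen_t i = 0; i < sz; ++i) r[i] *= invd[i];
    for (int z = 1; z < g.nz; ++z) {
      R_xlen_t pb = (R_xlen_t)z * sz;
      for (R_xlen_t q = 0; q < sz; ++q) {
        R_xlen_t i = pb + q;
        double sub = act[i] ? -h * gm[i] : 0.0;
        r[i] = (r[i] - sub * r[i - sz]) * invd[i];
      }
    }
    for (int z = g.nz - 2; z >= 0; --z) {
      R_xlen_t pb = (R_xlen_t)z * sz;
      for (R_xlen_t q = 0; q < sz; ++q) {
        R_xlen_t i = pb + q;
        r[i] -= w[i] * r[i + sz];
      }
    }
  }
}

// [[Rcpp::export(name = ".dgSolve")]]
List dgSolve(IntegerVector dims, NumericVector lambda, NumericVector invRhoC,
             NumericVector hb0, NumericVector pmet0, LogicalVector skin,
             LogicalVector active, double dx, double dt, int nSteps,
             double hAmb, bool robinAtBounds, NumericVector Pbase,
             IntegerVector metalIdx0, NumericMatrix M, NumericMatrix gram,
             IntegerVector snapshotSteps, NumericVector thresholds,
             double deltaB, double capDefault, double capSkin,
             double metBase, NumericVector u0) {
  Grid g{dims[0], dims[1], dims[2],
         (R_xlen_t)dims[0] * dims[1] * dims[2], dx};
  const double* lam = lambda.begin();
  const double* irc = invRhoC.begin();
  const int* act = active.begin();
  const int* sk = skin.begin();
  const double logMet = std::log(metBase);
  const double invDb = std::log(2.0) / deltaB;

  std::vector<double> gmx, gpx, robx, wx, invdx;
  std::vector<double> gmy, gpy, roby, wy, invdy;
  std::vector<double> gmz, gpz, robz, wz, invdz;
  precomputeDirection(g, 0, lam, irc, act, hAmb, robinAtBounds, dt,
                      gmx, gpx, robx, wx, invdx);
  precomputeDirection(g, 1, lam, irc, act, hAmb, robinAtBounds, dt,
                      gmy, gpy, roby, wy, invdy);
  precomputeDirection(g, 2, lam, irc, act, hAmb, robinAtBounds, dt,
                      gmz, gpz, robz, wz, invdz);

  std::vector<double> u(g.N, 0.0);
  if (u0.size() == g.N) std::copy(u0.begin(), u0.end(), u.begin());
  std::vector<double> P(Pbase.begin(), Pbase.end());
  std::vector<double> dxu(g.N), dyu(g.N), dzu(g.N), rhs(g.N);

  const int nSnap = snapshotSteps.size();
  NumericMatrix snapshots(nSnap > 0 ? g.N : 0, nSnap);
  NumericVector maxSeries(nSteps);
  const int nThr = thresholds.size();
  NumericMatrix crossTimes(nThr > 0 ? g.N : 0, nThr);
  std::fill(crossTimes.begin(), crossTimes.end(), NA_REAL);

  const R_xlen_t strideY = g.nx, strideZ = (R_xlen_t)g.nx * g.ny;
  int snapPos = 0;

  for (int s = 0; s < nSteps; ++s) {
    // per-step gradient-coil power on metal voxels
    if (metalIdx0.size() > 0) {
      for (int m = 0; m < metalIdx0.size(); ++m) {
        R_xlen_t i = metalIdx0[m];
        double p = Pbase[i];
        for (int c = 0; c < 6; ++c) p += M(m, c) * gram(s, c);
        P[i] = p;
      }
    }

    // explicit directional operators and source at time level n
    for (R_xlen_t i = 0; i < g.N; ++i) {
      if (!act[i]) { dxu[i] = dyu[i] = dzu[i] = 0.0; continue; }
      double ui = u[i];
      double ax = -(gmx[i] + gpx[i] + robx[i]) * ui;
      if (gmx[i] != 0.0) ax += gmx[i] * u[i - 1];
      if (gpx[i] != 0.0) ax += gpx[i] * u[i + 1];
      dxu[i] = ax;
      double ay = -(gmy[i] + gpy[i] + roby[i]) * ui;
      if (gmy[i] != 0.0) ay += gmy[i] * u[i - strideY];
      if (gpy[i] != 0.0) ay += gpy[i] * u[i + strideY];
      dyu[i] = ay;
      double az = -(gmz[i] + gpz[i] + robz[i]) * ui;
      if (gmz[i] != 0.0) az += gmz[i] * u[i - strideZ];
      if (gpz[i] != 0.0) az += gpz[i] * u[i + strideZ];
      dzu[i] = az;
    }

    for (R_xlen_t i = 0; i < g.N; ++i) {
      if (!act[i]) { rhs[i] = 0.0; continue; }
      double ui = u[i];
      double f = P[i];
      if (ui > 1e-300) {
        double lb = std::exp(ui * invDb);
        double cap = sk[i] ? capSkin : capDefault;
        if (lb > cap) lb = cap;
        f += -lb * hb0[i] * ui + std::expm1(ui * logMet) * pmet0[i];
      } else {
        f += -hb0[i] * ui;  // LB = 1 at or below zero increase
      }
      rhs[i] = ui + dt * (0.5 * dxu[i] + dyu[i] + dzu[i] + irc[i] * f);
    }

    thomasSolve(g, 0, gmx, wx, invdx, dt, act, rhs);     // -> u*
    for (R_xlen_t i = 0; i < g.N; ++i)
      if (act[i]) rhs[i] -= 0.5 * dt * dyu[i];
    thomasSolve(g, 1, gmy, wy, invdy, dt, act, rhs);     // -> u**
    for (R_xlen_t i = 0; i < g.N; ++i)
      if (act[i]) rhs[i] -= 0.5 * dt * dzu[i];
    thomasSolve(g, 2, gmz, wz, invdz, dt, act, rhs);     // -> u^{n+1}

    double mx = 0.0;
    for (R_xlen_t i = 0; i < g.N; ++i) {
      double un = act[i] ? rhs[i] : 0.0;
      if (!std::isfinite(un))
        stop("instability error: non-finite update at step %d, cell %ld "
             "(dt = %g)", s + 1, (long)i + 1, dt);
      for (int j = 0; j < nThr; ++j) {
        if (ISNA(crossTimes(i, j)) && un > thresholds[j]) {
          double prev = u[i];
          double frac = (un > prev) ? (thresholds[j] - prev) / (un - prev)
                                    : 1.0;
          if (frac < 0.0) frac = 0.0;
          if (frac > 1.0) frac = 1.0;
          crossTimes(i, j) = (s + frac) * dt;
        }
      }
      u[i] = un;
      if (un > mx) mx = un;
    }
    maxSeries[s] = mx;

    if (snapPos < nSnap && snapshotSteps[snapPos] == s + 1) {
      for (R_xlen_t i = 0; i < g.N; ++i) snapshots(i, snapPos) = u[i];
      ++snapPos;
    }
  }

  NumericVector uOut(u.begin(), u.end());
  return List::create(_["snapshots"] = snapshots,
                      _["maxSeries"] = maxSeries,
                      _["crossTimes"] = crossTimes, _["u"] = uOut);
}

// Plain explicit-Euler reference integrator for the same equation, used as
// an independent time-integration oracle on small grids. Constant power.
// [[Rcpp::export(name = ".eulerSolve")]]
NumericVector eulerSolve(IntegerVector dims, NumericVector lambda,
                         NumericVector invRhoC, NumericVector hb0,
                         NumericVector pmet0, LogicalVector skin,
                         LogicalVector active, double dx, double dt,
                         int nSteps, double hAmb, bool robinAtBounds,
                         NumericVector P, double deltaB, double capDefault,
                         double capSkin, double metBase) {
  Grid g{dims[0], dims[1], dims[2],
         (R_xlen_t)dims[0] * dims[1] * dims[2], dx};
  const double* lam = lambda.begin();
  const double* irc = invRhoC.begin();
  const int* act = active.begin();
  const int* sk = skin.begin();
  const double logMet = std::log(metBase);
  const double invDb = std::log(2.0) / deltaB;
  const R_xlen_t stride[3] = {1, (R_xlen_t)g.nx, (R_xlen_t)g.nx * g.ny};
  const int len[3] = {g.nx, g.ny, g.nz};

  std::vector<double> u(g.N, 0.0), un(g.N, 0.0);
  for (int s = 0; s < nSteps; ++s) {
    for (R_xlen_t i = 0; i < g.N; ++i) {
      if (!act[i]) { un[i] = 0.0; continue; }
      int pos[3];
      pos[0] = (int)(i % g.nx);
      pos[1] = (int)((i / g.nx) % g.ny);
      pos[2] = (int)(i / stride[2]);
      double lap = 0.0;
      for (int d = 0; d < 3; ++d) {
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          int p = pos[d] + sgn;
          bool inGrid = (p >= 0 && p < len[d]);
          R_xlen_t j = i + sgn * stride[d];
          if (inGrid && act[j]) {
            lap += faceCoef(lam, irc, i, j, g.dx) * (u[j] - u[i]);
          } else if (inGrid || robinAtBounds) {
            if (!inGrid || !act[j])
              lap -= robinCoef(lam, irc, i, g.dx, hAmb) * u[i];
          }
        }
      }
      double f = P[i];
      double ui = u[i];
      if (ui > 1e-300) {
        double lb = std::exp(ui * invDb);
        double cap = sk[i] ? capSkin : capDefault;
        if (lb > cap) lb = cap;
        f += -lb * hb0[i] * ui + std::expm1(ui * logMet) * pmet0[i];
      } else {
        f += -hb0[i] * ui;
      }
      un[i] = ui + dt * (lap + irc[i] * f);
    }
    std::swap(u, un);
  }
  return NumericVector(u.begin(), u.end());
}
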