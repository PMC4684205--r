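// Staggered (MAC) grid kernels: semi-Lagrangian / BFECC advection,
// divergence, and the coupled pressure solve.
//
// Velocity components live on faces: u (nx+1, ny, nz), v (nx, ny+1, nz),
// w (nx, ny, nz+1); pressure on cell centers.  Positions are in domain
// coordinates with the corner at (0,0,0).
//
// The coupled solve is a matrix-free preconditioned conjugate gradient on
//   A p = (dt*dx/rho) L p + dt * E M^-1 E^T p = b
// where L is the standard 7-point Laplacian over fluid cells (Neumann at
// walls and solid cells, Dirichlet p=0 above the top plane) and E maps
// cell pressures to generalized forces on the articulated body through the
// volume-fraction weighted pressure-area terms of the coupled faces.  The
// preconditioner is modified incomplete Cholesky MIC(0) on the Laplacian
// part.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Dims { int nx, ny, nz; };

static inline int cidx(const Dims& d, int i, int j, int k) {
  return i + d.nx * (j + d.ny * k);
}
static inline int uidx(const Dims& d, int i, int j, int k) {
  return i + (d.nx + 1) * (j + d.ny * k);
}
static inline int vidx(const Dims& d, int i, int j, int k) {
  return i + d.nx * (j + (d.ny + 1) * k);
}
static inline int widx(const Dims& d, int i, int j, int k) {
  return i + d.nx * (j + d.ny * k);  // (nx, ny, nz+1): same slab stride
}

// trilinear sample of a component grid with sizes (sx,sy,sz) and face
// offsets (ox,oy,oz) in units of dx; optionally records the local 8-corner
// min/max for BFECC clamping
static double sample_comp(const double* f, int sx, int sy, int sz,
                          double ox, double oy, double oz, double dx,
                          double px, double py, double pz,
                          double* mn = nullptr, double* mx = nullptr) {
  double gx = px / dx - ox, gy = py / dx - oy, gz = pz / dx - oz;
  gx = std::min(std::max(gx, 0.0), sx - 1.000001);
  gy = std::min(std::max(gy, 0.0), sy - 1.000001);
  gz = std::min(std::max(gz, 0.0), sz - 1.000001);
  int i = (int)gx, j = (int)gy, k = (int)gz;
  double fx = gx - i, fy = gy - j, fz = gz - k;
  double acc = 0, lo = R_PosInf, hi = R_NegInf;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double val = f[(i + di) + sx * ((j + dj) + sy * (k + dk))];
        double wgt = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        acc += wgt * val;
        lo = std::min(lo, val);
        hi = std::max(hi, val);
      }
  if (mn) *mn = lo;
  if (mx) *mx = hi;
  return acc;
}

static double sample_fast(const double* f, int sx, int sy, int sz,
                          double ox, double oy, double oz, double dx,
                          double px, double py, double pz) {
  double gx = px / dx - ox, gy = py / dx - oy, gz = pz / dx - oz;
  gx = std::min(std::max(gx, 0.0), sx - 1.000001);
  gy = std::min(std::max(gy, 0.0), sy - 1.000001);
  gz = std::min(std::max(gz, 0.0), sz - 1.000001);
  int i = (int)gx, j = (int)gy, k = (int)gz;
  double fx = gx - i, fy = gy - j, fz = gz - k;
  const double* p0 = f + i + sx * (j + sy * k);
  double c00 = p0[0] + fx * (p0[1] - p0[0]);
  double c10 = p0[sx] + fx * (p0[sx + 1] - p0[sx]);
  const double* p1 = p0 + sx * sy;
  double c01 = p1[0] + fx * (p1[1] - p1[0]);
  double c11 = p1[sx] + fx * (p1[sx + 1] - p1[sx]);
  double c0 = c00 + fy * (c10 - c00);
  double c1 = c01 + fy * (c11 - c01);
  return c0 + fz * (c1 - c0);
}

struct MacField {
  const double *u, *v, *w;
  Dims d;
  double dx;
  void vel(double px, double py, double pz, double* out) const {
    out[0] = sample_fast(u, d.nx + 1, d.ny, d.nz, 0.0, 0.5, 0.5, dx, px, py, pz);
    out[1] = sample_fast(v, d.nx, d.ny + 1, d.nz, 0.5, 0.0, 0.5, dx, px, py, pz);
    out[2] = sample_fast(w, d.nx, d.ny, d.nz + 1, 0.5, 0.5, 0.0, dx, px, py, pz);
  }
};

// back-traced sample positions for every face of every component
static void compute_traces(const MacField& adv, double dt,
                           std::vector<double>& tx, std::vector<double>& ty,
                           std::vector<double>& tz) {
  const Dims& d = adv.d;
  const double dx = adv.dx;
  double vel1[3], vel2[3];
  size_t nu = (size_t)(d.nx + 1) * d.ny * d.nz;
  size_t nv = (size_t)d.nx * (d.ny + 1) * d.nz;
  size_t nw = (size_t)d.nx * d.ny * (d.nz + 1);
  tx.resize(nu + nv + nw); ty.resize(nu + nv + nw); tz.resize(nu + nv + nw);
  size_t idx = 0;
  for (int comp = 0; comp < 3; ++comp) {
    int sx = d.nx + (comp == 0), sy = d.ny + (comp == 1),
        sz = d.nz + (comp == 2);
    double ox = comp == 0 ? 0.0 : 0.5, oy = comp == 1 ? 0.0 : 0.5,
           oz = comp == 2 ? 0.0 : 0.5;
    for (int k = 0; k < sz; ++k)
      for (int j = 0; j < sy; ++j)
        for (int i = 0; i < sx; ++i, ++idx) {
          double px = (i + ox) * dx, py = (j + oy) * dx, pz = (k + oz) * dx;
          adv.vel(px, py, pz, vel1);
          adv.vel(px - 0.5 * dt * vel1[0], py - 0.5 * dt * vel1[1],
                  pz - 0.5 * dt * vel1[2], vel2);
          tx[idx] = px - dt * vel2[0];
          ty[idx] = py - dt * vel2[1];
          tz[idx] = pz - dt * vel2[2];
        }
  }
}

// gather a component field at precomputed trace positions
static void gather_pass(const Dims& d, double dx, const double* su,
                        const double* sv, const double* sw,
                        const std::vector<double>& tx,
                        const std::vector<double>& ty,
                        const std::vector<double>& tz, double* ou,
                        double* ov, double* ow, const double* cu,
                        const double* cv, const double* cw) {
  size_t nu = (size_t)(d.nx + 1) * d.ny * d.nz;
  size_t nv = (size_t)d.nx * (d.ny + 1) * d.nz;
  size_t nw = (size_t)d.nx * d.ny * (d.nz + 1);
  for (size_t f = 0; f < nu; ++f) {
    double val = sample_fast(su, d.nx + 1, d.ny, d.nz, 0.0, 0.5, 0.5, dx,
                             tx[f], ty[f], tz[f]);
    if (cu) {
      double mn, mx;
      sample_comp(cu, d.nx + 1, d.ny, d.nz, 0.0, 0.5, 0.5, dx, tx[f], ty[f],
                  tz[f], &mn, &mx);
      val = std::min(std::max(val, mn), mx);
    }
    ou[f] = val;
  }
  for (size_t f = 0; f < nv; ++f) {
    size_t g = nu + f;
    double val = sample_fast(sv, d.nx, d.ny + 1, d.nz, 0.5, 0.0, 0.5, dx,
                             tx[g], ty[g], tz[g]);
    if (cv) {
      double mn, mx;
      sample_comp(cv, d.nx, d.ny + 1, d.nz, 0.5, 0.0, 0.5, dx, tx[g], ty[g],
                  tz[g], &mn, &mx);
      val = std::min(std::max(val, mn), mx);
    }
    ov[f] = val;
  }
  for (size_t f = 0; f < nw; ++f) {
    size_t g = nu + nv + f;
    double val = sample_fast(sw, d.nx, d.ny, d.nz + 1, 0.5, 0.5, 0.0, dx,
                             tx[g], ty[g], tz[g]);
    if (cw) {
      double mn, mx;
      sample_comp(cw, d.nx, d.ny, d.nz + 1, 0.5, 0.5, 0.0, dx, tx[g], ty[g],
                  tz[g], &mn, &mx);
      val = std::min(std::max(val, mn), mx);
    }
    ow[f] = val;
  }
}

// [[Rcpp::export]]
List cpp_advect_velocity(NumericVector u, NumericVector v, NumericVector w,
                         IntegerVector n, double dx, double dt,
                         bool bfecc) {
  Dims d = {n[0], n[1], n[2]};
  MacField adv = {u.begin(), v.begin(), w.begin(), d, dx};
  size_t nu = u.size(), nv = v.size(), nw = w.size();
  NumericVector ou(nu), ov(nv), ow(nw);
  std::vector<double> txf, tyf, tzf;
  compute_traces(adv, dt, txf, tyf, tzf);  // forward traces, reused twice
  if (!bfecc) {
    gather_pass(d, dx, u.begin(), v.begin(), w.begin(), txf, tyf, tzf,
                ou.begin(), ov.begin(), ow.begin(), nullptr, nullptr,
                nullptr);
    return List::create(_["u"] = ou, _["v"] = ov, _["w"] = ow);
  }
  std::vector<double> f1u(nu), f1v(nv), f1w(nw), f2u(nu), f2v(nv), f2w(nw);
  std::vector<double> fsu(nu), fsv(nv), fsw(nw);
  gather_pass(d, dx, u.begin(), v.begin(), w.begin(), txf, tyf, tzf,
              f1u.data(), f1v.data(), f1w.data(), nullptr, nullptr, nullptr);
  {
    std::vector<double> txb, tyb, tzb;
    compute_traces(adv, -dt, txb, tyb, tzb);
    gather_pass(d, dx, f1u.data(), f1v.data(), f1w.data(), txb, tyb, tzb,
                f2u.data(), f2v.data(), f2w.data(), nullptr, nullptr,
                nullptr);
  }
  for (size_t i = 0; i < nu; ++i) fsu[i] = u[i] + 0.5 * (u[i] - f2u[i]);
  for (size_t i = 0; i < nv; ++i) fsv[i] = v[i] + 0.5 * (v[i] - f2v[i]);
  for (size_t i = 0; i < nw; ++i) fsw[i] = w[i] + 0.5 * (w[i] - f2w[i]);
  gather_pass(d, dx, fsu.data(), fsv.data(), fsw.data(), txf, tyf, tzf,
              ou.begin(), ov.begin(), ow.begin(), u.begin(), v.begin(),
              w.begin());
  return List::create(_["u"] = ou, _["v"] = ov, _["w"] = ow);
}

// cell-centered scalar advection (used for tracer tests and diagnostics)
// [[Rcpp::export]]
NumericVector cpp_advect_scalar(NumericVector phi, NumericVector u,
                                NumericVector v, NumericVector w,
                                IntegerVector n, double dx, double dt,
                                bool bfecc) {
  Dims d = {n[0], n[1], n[2]};
  MacField adv = {u.begin(), v.begin(), w.begin(), d, dx};
  size_t nc = phi.size();
  auto pass = [&](const double* src, double sdt, double* out, bool clamp) {
    double vel1[3], vel2[3];
    for (int k = 0; k < d.nz; ++k)
      for (int j = 0; j < d.ny; ++j)
        for (int i = 0; i < d.nx; ++i) {
          double px = (i + 0.5) * dx, py = (j + 0.5) * dx, pz = (k + 0.5) * dx;
          adv.vel(px, py, pz, vel1);
          adv.vel(px - 0.5 * sdt * vel1[0], py - 0.5 * sdt * vel1[1],
                  pz - 0.5 * sdt * vel1[2], vel2);
          double bx = px - sdt * vel2[0], by = py - sdt * vel2[1],
                 bz = pz - sdt * vel2[2];
          double mn, mx;
          double val = sample_comp(src, d.nx, d.ny, d.nz, 0.5, 0.5, 0.5, dx,
                                   bx, by, bz, &mn, &mx);
          if (clamp) {
            sample_comp(phi.begin(), d.nx, d.ny, d.nz, 0.5, 0.5, 0.5, dx, bx,
                        by, bz, &mn, &mx);
            val = std::min(std::max(val, mn), mx);
          }
          out[cidx(d, i, j, k)] = val;
        }
  };
  NumericVector out(nc);
  if (!bfecc) {
    pass(phi.begin(), dt, out.begin(), false);
    return out;
  }
  std::vector<double> f1(nc), f2(nc), fs(nc);
  pass(phi.begin(), dt, f1.data(), false);
  pass(f1.data(), -dt, f2.data(), false);
  for (size_t i = 0; i < nc; ++i) fs[i] = phi[i] + 0.5 * (phi[i] - f2[i]);
  pass(fs.data(), dt, out.begin(), true);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_divergence(NumericVector u, NumericVector v, NumericVector w,
                             IntegerVector n, double dx) {
  Dims d = {n[0], n[1], n[2]};
  NumericVector out(d.nx * d.ny * d.nz);
  for (int k = 0; k < d.nz; ++k)
    for (int j = 0; j < d.ny; ++j)
      for (int i = 0; i < d.nx; ++i)
        out[cidx(d, i, j, k)] =
          (u[uidx(d, i + 1, j, k)] - u[uidx(d, i, j, k)] +
           v[vidx(d, i, j + 1, k)] - v[vidx(d, i, j, k)] +
           w[widx(d, i, j, k + 1)] - w[widx(d, i, j, k)]) / dx;
  return out;
}

// ---------------------------------------------------------------------------
// coupled pressure solve

struct CoupleData {
  int k, nlink, nd;
  const int* fcell;
  const double* fw;      // v_i * dx^2
  const double *m0, *m1, *m2;  // face normal into solid
  const double *d0, *d1, *d2;  // face point minus link COM
  const int* flink;
  const double* L;    // (6*nlink) x 18, column-major
  const double* Minv; // 18x18 column-major
};

// tau = E^T p  (generalized force, ndof-vector)
static void etp(const CoupleData& cd, const double* p, double* tau) {
  std::vector<double> f(6 * cd.nlink, 0.0);
  for (int i = 0; i < cd.k; ++i) {
    double coef = cd.fw[i] * p[cd.fcell[i]];
    if (coef == 0.0) continue;
    double m[3] = {cd.m0[i], cd.m1[i], cd.m2[i]};
    double dd[3] = {cd.d0[i], cd.d1[i], cd.d2[i]};
    double* fl = &f[6 * cd.flink[i]];
    fl[0] += coef * m[0];
    fl[1] += coef * m[1];
    fl[2] += coef * m[2];
    fl[3] += coef * (dd[1] * m[2] - dd[2] * m[1]);
    fl[4] += coef * (dd[2] * m[0] - dd[0] * m[2]);
    fl[5] += coef * (dd[0] * m[1] - dd[1] * m[0]);
  }
  for (int c = 0; c < cd.nd; ++c) {
    double acc = 0;
    for (int l = 0; l < cd.nlink; ++l) {
      const double* fl = &f[6 * l];
      for (int r = 0; r < 6; ++r) acc += cd.L[(6 * l + r) + (6 * cd.nlink) * c] * fl[r];
    }
    tau[c] = acc;
  }
}

// out[cell] += dt * E (Minv tau); also needs per-link z = L_l y
static void e_apply(const CoupleData& cd, const double* y, double dt,
                    double* out) {
  std::vector<double> z(6 * cd.nlink, 0.0);
  for (int l = 0; l < cd.nlink; ++l)
    for (int r = 0; r < 6; ++r) {
      double acc = 0;
      for (int c = 0; c < cd.nd; ++c) acc += cd.L[(6 * l + r) + (6 * cd.nlink) * c] * y[c];
      z[6 * l + r] = acc;
    }
  for (int i = 0; i < cd.k; ++i) {
    const double* zl = &z[6 * cd.flink[i]];
    double dd[3] = {cd.d0[i], cd.d1[i], cd.d2[i]};
    double vx = zl[0] + zl[4] * dd[2] - zl[5] * dd[1];
    double vy = zl[1] + zl[5] * dd[0] - zl[3] * dd[2];
    double vz = zl[2] + zl[3] * dd[1] - zl[4] * dd[0];
    double val = cd.m0[i] * vx + cd.m1[i] * vy + cd.m2[i] * vz;
    out[cd.fcell[i]] += dt * cd.fw[i] * val;
  }
}

// [[Rcpp::export]]
List cpp_solve_pressure(IntegerVector n, double dx, double dt, double rho,
                        IntegerVector fluid, bool top_dirichlet,
                        NumericVector b, NumericVector wu, NumericVector wv,
                        NumericVector ww, IntegerVector fcell,
                        NumericVector fw, NumericMatrix fm, NumericMatrix fd,
                        IntegerVector flink, NumericMatrix Lmat,
                        NumericMatrix Minv, double rtol, double atol,
                        int maxit) {
  Dims d = {n[0], n[1], n[2]};
  int ncell = d.nx * d.ny * d.nz;
  const double s0 = dt * dx / rho;
  const int K = fcell.size();
  const int nlink = (K > 0) ? Lmat.nrow() / 6 : 0;
  const int ND = (K > 0) ? Minv.nrow() : 0;
  CoupleData cd = {K, nlink, ND, fcell.begin(), fw.begin(),
                   (K ? &fm(0, 0) : nullptr), (K ? &fm(0, 1) : nullptr),
                   (K ? &fm(0, 2) : nullptr), (K ? &fd(0, 0) : nullptr),
                   (K ? &fd(0, 1) : nullptr), (K ? &fd(0, 2) : nullptr),
                   flink.begin(), (K ? Lmat.begin() : nullptr),
                   (K ? Minv.begin() : nullptr)};

  const int* fl = fluid.begin();
  auto isfluid = [&](int i, int j, int k) {
    if (i < 0 || i >= d.nx || j < 0 || j >= d.ny || k < 0 || k >= d.nz)
      return false;
    return fl[cidx(d, i, j, k)] != 0;
  };
  // fluid-area weight of the face between cell (i,j,k) and its +dir
  // neighbor (dir 0,1,2 = x,y,z); already zeroed by the caller on faces
  // without a pressure connection
  auto wface = [&](int i, int j, int k, int dir) -> double {
    if (dir == 0) return wu[uidx(d, i + 1, j, k)];
    if (dir == 1) return wv[vidx(d, i, j + 1, k)];
    return ww[i + d.nx * (j + d.ny * (k + 1))];
  };
  // weight of the face between (i,j,k) and its neighbor at offset
  auto wlink = [&](int i, int j, int k, int di, int dj, int dk) -> double {
    if (di == -1) return wu[uidx(d, i, j, k)];
    if (di == +1) return wu[uidx(d, i + 1, j, k)];
    if (dj == -1) return wv[vidx(d, i, j, k)];
    if (dj == +1) return wv[vidx(d, i, j + 1, k)];
    if (dk == -1) return ww[i + d.nx * (j + d.ny * k)];
    return ww[i + d.nx * (j + d.ny * (k + 1))];
  };

  // weighted Laplacian diagonal
  std::vector<double> diag(ncell, 0.0);
  for (int k = 0; k < d.nz; ++k)
    for (int j = 0; j < d.ny; ++j)
      for (int i = 0; i < d.nx; ++i) {
        int c = cidx(d, i, j, k);
        if (!fl[c]) continue;
        double nd = 0;
        if (isfluid(i - 1, j, k)) nd += wlink(i, j, k, -1, 0, 0);
        if (isfluid(i + 1, j, k)) nd += wlink(i, j, k, +1, 0, 0);
        if (isfluid(i, j - 1, k)) nd += wlink(i, j, k, 0, -1, 0);
        if (isfluid(i, j + 1, k)) nd += wlink(i, j, k, 0, +1, 0);
        if (isfluid(i, j, k - 1)) nd += wlink(i, j, k, 0, 0, -1);
        if (isfluid(i, j, k + 1)) nd += wlink(i, j, k, 0, 0, +1);
        // free surface at the top plane: p = 0 half a cell above the top
        // cell center (ghost value -p), hence coefficient 2
        if (top_dirichlet && k == d.nz - 1)
          nd += 2.0 * ww[i + d.nx * (j + d.ny * d.nz)];
        diag[c] = nd;
      }

  // MIC(0) preconditioner on the weighted Laplacian part
  const double tau_mic = 0.97, sigma = 0.25;
  std::vector<double> precon(ncell, 0.0);
  for (int k = 0; k < d.nz; ++k)
    for (int j = 0; j < d.ny; ++j)
      for (int i = 0; i < d.nx; ++i) {
        int c = cidx(d, i, j, k);
        if (!fl[c]) continue;
        double e = diag[c];
        // lower neighbors (q: 0 = x-1, 1 = y-1, 2 = z-1)
        for (int q = 0; q < 3; ++q) {
          int ni = i - (q == 0), nj = j - (q == 1), nk = k - (q == 2);
          if (!isfluid(ni, nj, nk)) continue;
          int nb = cidx(d, ni, nj, nk);
          double aq = -wface(ni, nj, nk, q);   // A(nb -> this row)
          e -= (aq * precon[nb]) * (aq * precon[nb]);
          // dropped fill-in row sums (modified IC)
          double others = 0.0;
          if (q != 0 && isfluid(ni + 1, nj, nk)) others += -wface(ni, nj, nk, 0);
          if (q != 1 && isfluid(ni, nj + 1, nk)) others += -wface(ni, nj, nk, 1);
          if (q != 2 && isfluid(ni, nj, nk + 1)) others += -wface(ni, nj, nk, 2);
          e -= tau_mic * aq * others * precon[nb] * precon[nb];
        }
        if (e < sigma * diag[c]) e = diag[c];
        precon[c] = (e > 0) ? 1.0 / std::sqrt(e) : 0.0;
      }

  auto apply_precon = [&](const std::vector<double>& r, std::vector<double>& z,
                          std::vector<double>& qtmp) {
    // solve L q = r (forward), L^T z = q (backward)
    for (int k = 0; k < d.nz; ++k)
      for (int j = 0; j < d.ny; ++j)
        for (int i = 0; i < d.nx; ++i) {
          int c = cidx(d, i, j, k);
          if (!fl[c]) { qtmp[c] = 0; continue; }
          double t = r[c];
          if (isfluid(i - 1, j, k))
            t += wface(i - 1, j, k, 0) * precon[cidx(d, i - 1, j, k)] *
                 qtmp[cidx(d, i - 1, j, k)];
          if (isfluid(i, j - 1, k))
            t += wface(i, j - 1, k, 1) * precon[cidx(d, i, j - 1, k)] *
                 qtmp[cidx(d, i, j - 1, k)];
          if (isfluid(i, j, k - 1))
            t += wface(i, j, k - 1, 2) * precon[cidx(d, i, j, k - 1)] *
                 qtmp[cidx(d, i, j, k - 1)];
          qtmp[c] = t * precon[c];
        }
    for (int k = d.nz - 1; k >= 0; --k)
      for (int j = d.ny - 1; j >= 0; --j)
        for (int i = d.nx - 1; i >= 0; --i) {
          int c = cidx(d, i, j, k);
          if (!fl[c]) { z[c] = 0; continue; }
          double t = qtmp[c];
          if (isfluid(i + 1, j, k))
            t += wface(i, j, k, 0) * precon[c] * z[cidx(d, i + 1, j, k)];
          if (isfluid(i, j + 1, k))
            t += wface(i, j, k, 1) * precon[c] * z[cidx(d, i, j + 1, k)];
          if (isfluid(i, j, k + 1))
            t += wface(i, j, k, 2) * precon[c] * z[cidx(d, i, j, k + 1)];
          z[c] = t * precon[c];
        }
  };

  auto apply_A = [&](const std::vector<double>& p, std::vector<double>& out) {
    for (int k = 0; k < d.nz; ++k)
      for (int j = 0; j < d.ny; ++j)
        for (int i = 0; i < d.nx; ++i) {
          int c = cidx(d, i, j, k);
          if (!fl[c]) { out[c] = 0; continue; }
          double acc = diag[c] * p[c];
          if (isfluid(i - 1, j, k))
            acc -= wlink(i, j, k, -1, 0, 0) * p[cidx(d, i - 1, j, k)];
          if (isfluid(i + 1, j, k))
            acc -= wlink(i, j, k, +1, 0, 0) * p[cidx(d, i + 1, j, k)];
          if (isfluid(i, j - 1, k))
            acc -= wlink(i, j, k, 0, -1, 0) * p[cidx(d, i, j - 1, k)];
          if (isfluid(i, j + 1, k))
            acc -= wlink(i, j, k, 0, +1, 0) * p[cidx(d, i, j + 1, k)];
          if (isfluid(i, j, k - 1))
            acc -= wlink(i, j, k, 0, 0, -1) * p[cidx(d, i, j, k - 1)];
          if (isfluid(i, j, k + 1))
            acc -= wlink(i, j, k, 0, 0, +1) * p[cidx(d, i, j, k + 1)];
          out[c] = s0 * acc;
        }
    if (K > 0) {
      std::vector<double> tauv(ND), yv(ND);
      etp(cd, p.data(), tauv.data());
      for (int r = 0; r < ND; ++r) {
        double acc = 0;
        for (int c = 0; c < ND; ++c) acc += cd.Minv[r + ND * c] * tauv[c];
        yv[r] = acc;
      }
      e_apply(cd, yv.data(), dt, out.data());
    }
  };

  // PCG
  std::vector<double> p(ncell, 0.0), r(ncell, 0.0), z(ncell, 0.0),
      s(ncell, 0.0), Ap(ncell, 0.0), qtmp(ncell, 0.0);
  double bmax = 0;
  for (int c = 0; c < ncell; ++c)
    if (fl[c]) { r[c] = b[c]; bmax = std::max(bmax, std::fabs(b[c])); }
  double tol = std::max(atol, rtol * bmax);
  int it = 0;
  double rmax = bmax;
  if (bmax > tol) {
    apply_precon(r, z, qtmp);
    s = z;
    double sigma_rz = 0;
    for (int c = 0; c < ncell; ++c) sigma_rz += r[c] * z[c];
    for (it = 1; it <= maxit; ++it) {
      apply_A(s, Ap);
      double sAs = 0;
      for (int c = 0; c < ncell; ++c) sAs += s[c] * Ap[c];
      if (sAs == 0) break;
      double alpha = sigma_rz / sAs;
      rmax = 0;
      for (int c = 0; c < ncell; ++c) {
        p[c] += alpha * s[c];
        r[c] -= alpha * Ap[c];
        rmax = std::max(rmax, std::fabs(r[c]));
      }
      if (rmax <= tol) break;
      apply_precon(r, z, qtmp);
      double sigma_new = 0;
      for (int c = 0; c < ncell; ++c) sigma_new += r[c] * z[c];
      double beta = sigma_new / sigma_rz;
      sigma_rz = sigma_new;
      for (int c = 0; c < ncell; ++c) s[c] = z[c] + beta * s[c];
    }
  }

  NumericVector pressure(p.begin(), p.end());
  NumericVector tau(std::max(ND, 1));
  if (K > 0) {
    std::vector<double> tauv(ND);
    etp(cd, p.data(), tauv.data());
    for (int i = 0; i < ND; ++i) tau[i] = tauv[i];
  }
  return List::create(_["p"] = pressure, _["tau"] = tau, _["iter"] = it,
                      _["resid"] = rmax, _["tol"] = tol);
}

// sample the MAC velocity at arbitrary points (domain-corner coordinates)
// [[Rcpp::export]]
NumericMatrix cpp_interp_velocity(NumericVector u, NumericVector v,
                                  NumericVector w, IntegerVector n,
                                  double dx, NumericMatrix pts) {
  Dims d = {n[0], n[1], n[2]};
  MacField adv = {u.begin(), v.begin(), w.begin(), d, dx};
  NumericMatrix out(pts.nrow(), 3);
  double vel[3];
  for (int i = 0; i < pts.nrow(); ++i) {
    adv.vel(pts(i, 0), pts(i, 1), pts(i, 2), vel);
    out(i, 0) = vel[0];
    out(i, 1) = vel[1];
    out(i, 2) = vel[2];
  }
  return out;
}

// apply the coupled pressure operator A = (dt*dx/rho) L_w + dt E M^-1 E^T
// to a given vector (exposed for symmetry / positive-semidefiniteness and
// reduction checks in the tests)
// [[Rcpp::export]]
NumericVector cpp_apply_coupled_operator(IntegerVector n, double dx,
                                         double dt, double rho,
                                         IntegerVector fluid,
                                         bool top_dirichlet,
                                         NumericVector wu, NumericVector wv,
                                         NumericVector ww,
                                         IntegerVector fcell,
                                         NumericVector fw, NumericMatrix fm,
                                         NumericMatrix fd,
                                         IntegerVector flink,
                                         NumericMatrix Lmat,
                                         NumericMatrix Minv,
                                         NumericVector pvec) {
  Dims d = {n[0], n[1], n[2]};
  int ncell = d.nx * d.ny * d.nz;
  const double s0 = dt * dx / rho;
  const int K = fcell.size();
  const int nlink = (K > 0) ? Lmat.nrow() / 6 : 0;
  const int ND = (K > 0) ? Minv.nrow() : 0;
  CoupleData cd = {K, nlink, ND, fcell.begin(), fw.begin(),
                   (K ? &fm(0, 0) : nullptr), (K ? &fm(0, 1) : nullptr),
                   (K ? &fm(0, 2) : nullptr), (K ? &fd(0, 0) : nullptr),
                   (K ? &fd(0, 1) : nullptr), (K ? &fd(0, 2) : nullptr),
                   flink.begin(), (K ? Lmat.begin() : nullptr),
                   (K ? Minv.begin() : nullptr)};
  const int* fl = fluid.begin();
  auto isfluid = [&](int i, int j, int k) {
    if (i < 0 || i >= d.nx || j < 0 || j >= d.ny || k < 0 || k >= d.nz)
      return false;
    return fl[cidx(d, i, j, k)] != 0;
  };
  auto wlink = [&](int i, int j, int k, int di, int dj, int dk) -> double {
    if (di == -1) return wu[uidx(d, i, j, k)];
    if (di == +1) return wu[uidx(d, i + 1, j, k)];
    if (dj == -1) return wv[vidx(d, i, j, k)];
    if (dj == +1) return wv[vidx(d, i, j + 1, k)];
    if (dk == -1) return ww[i + d.nx * (j + d.ny * k)];
    return ww[i + d.nx * (j + d.ny * (k + 1))];
  };
  NumericVector out(ncell);
  std::vector<double> p(pvec.begin(), pvec.end());
  for (int k = 0; k < d.nz; ++k)
    for (int j = 0; j < d.ny; ++j)
      for (int i = 0; i < d.nx; ++i) {
        int c = cidx(d, i, j, k);
        if (!fl[c]) { out[c] = 0; continue; }
        double nd = 0, acc = 0;
        if (isfluid(i - 1, j, k)) {
          double w = wlink(i, j, k, -1, 0, 0);
          nd += w; acc -= w * p[cidx(d, i - 1, j, k)];
        }
        if (isfluid(i + 1, j, k)) {
          double w = wlink(i, j, k, +1, 0, 0);
          nd += w; acc -= w * p[cidx(d, i + 1, j, k)];
        }
        if (isfluid(i, j - 1, k)) {
          double w = wlink(i, j, k, 0, -1, 0);
          nd += w; acc -= w * p[cidx(d, i, j - 1, k)];
        }
        if (isfluid(i, j + 1, k)) {
          double w = wlink(i, j, k, 0, +1, 0);
          nd += w; acc -= w * p[cidx(d, i, j + 1, k)];
        }
        if (isfluid(i, j, k - 1)) {
          double w = wlink(i, j, k, 0, 0, -1);
          nd += w; acc -= w * p[cidx(d, i, j, k - 1)];
        }
        if (isfluid(i, j, k + 1)) {
          double w = wlink(i, j, k, 0, 0, +1);
          nd += w; acc -= w * p[cidx(d, i, j, k + 1)];
        }
        if (top_dirichlet && k == d.nz - 1)
          nd += 2.0 * ww[i + d.nx * (j + d.ny * d.nz)];
        out[c] = s0 * (nd * p[c] + acc);
      }
  if (K > 0) {
    std::vector<double> tauv(ND), yv(ND);
    etp(cd, p.data(), tauv.data());
    for (int r = 0; r < ND; ++r) {
      double acc = 0;
      for (int c2 = 0; c2 < ND; ++c2) acc += cd.Minv[r + ND * c2] * tauv[c2];
      yv[r] = acc;
    }
    e_apply(cd, yv.data(), dt, REAL(out));
  }
  return out;
}
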