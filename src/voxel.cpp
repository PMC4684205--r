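// Ray-parity inside/outside tests and sub-grid voxelization of triangle
// meshes onto a regular grid.
//
// Cell-center coordinates are always computed as (i + 0.5 - N/2)*h + center
// so that, for a grid whose lateral center is exactly 0, sample positions
// are exact floating-point negations of their mirror images.  Combined with
// the sign-symmetry of the Moller-Trumbore arithmetic this makes voxel
// labels and fractions of a sagittally mirrored body exact mirrors.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}
static inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1]*b[2] - a[2]*b[1];
  o[1] = a[2]*b[0] - a[0]*b[2];
  o[2] = a[0]*b[1] - a[1]*b[0];
}

// Moller-Trumbore. Returns 1 hit, 0 miss, -1 degenerate (near edge/vertex,
// or ray nearly in the triangle plane): caller must jitter and retry.
static int ray_tri(const double* o, const double* d,
                   const double* a, const double* b, const double* c,
                   double& t) {
  double e1[3], e2[3], sv[3], pv[3], qv[3];
  for (int i = 0; i < 3; ++i) {
    e1[i] = b[i] - a[i];
    e2[i] = c[i] - a[i];
    sv[i] = o[i] - a[i];
  }
  cross3(d, e2, pv);
  double det = dot3(e1, pv);
  double l1 = std::sqrt(dot3(e1, e1)), l2 = std::sqrt(dot3(e2, e2));
  double ld = std::sqrt(dot3(d, d));
  double scale = l1 * l2 * ld;
  if (std::fabs(det) <= 1e-12 * scale) {
    // ray parallel to plane: degenerate only if origin is essentially in it
    double nrm[3];
    cross3(e1, e2, nrm);
    double ln = std::sqrt(dot3(nrm, nrm));
    if (ln <= 0) return 0;  // degenerate triangle: ignore
    double dist = std::fabs(dot3(nrm, sv)) / ln;
    return (dist <= 1e-9 * std::max(l1, l2)) ? -1 : 0;
  }
  double inv = 1.0 / det;
  double u = dot3(sv, pv) * inv;
  cross3(sv, e1, qv);
  double v = dot3(d, qv) * inv;
  const double eb = 1e-9;
  if (u < -eb || v < -eb || u + v > 1.0 + eb) return 0;
  if (u < eb || v < eb || u + v > 1.0 - eb) return -1;  // grazes an edge
  t = dot3(e2, qv) * inv / ld;  // distance along unit-normalized d
  return 1;
}

struct Bins2D {
  // triangle index lists binned over the two axes perpendicular to the ray
  int nb1, nb2;
  double min1, min2, inv1, inv2;
  std::vector<int> start;  // CSR offsets, size nb1*nb2+1
  std::vector<int> tri;
};

// bin triangles of (V,F) by bbox cover over axes (ax1, ax2)
static void build_bins(const NumericMatrix& V, const IntegerMatrix& F,
                       int ax1, int ax2, int nb1, int nb2, Bins2D& bins) {
  int nt = F.nrow();
  double lo1 = R_PosInf, hi1 = R_NegInf, lo2 = R_PosInf, hi2 = R_NegInf;
  for (int i = 0; i < V.nrow(); ++i) {
    lo1 = std::min(lo1, V(i, ax1)); hi1 = std::max(hi1, V(i, ax1));
    lo2 = std::min(lo2, V(i, ax2)); hi2 = std::max(hi2, V(i, ax2));
  }
  double pad1 = 1e-9 * (hi1 - lo1 + 1.0), pad2 = 1e-9 * (hi2 - lo2 + 1.0);
  lo1 -= pad1; hi1 += pad1; lo2 -= pad2; hi2 += pad2;
  bins.nb1 = nb1; bins.nb2 = nb2;
  bins.min1 = lo1; bins.min2 = lo2;
  bins.inv1 = nb1 / std::max(hi1 - lo1, 1e-12);
  bins.inv2 = nb2 / std::max(hi2 - lo2, 1e-12);
  std::vector<int> cnt(nb1 * nb2 + 1, 0);
  std::vector<int> r1a(nt), r1b(nt), r2a(nt), r2b(nt);
  for (int tIdx = 0; tIdx < nt; ++tIdx) {
    double a1 = R_PosInf, b1 = R_NegInf, a2 = R_PosInf, b2 = R_NegInf;
    for (int k = 0; k < 3; ++k) {
      int vi = F(tIdx, k) - 1;
      a1 = std::min(a1, V(vi, ax1)); b1 = std::max(b1, V(vi, ax1));
      a2 = std::min(a2, V(vi, ax2)); b2 = std::max(b2, V(vi, ax2));
    }
    int i1a = std::max(0, (int)std::floor((a1 - lo1) * bins.inv1));
    int i1b = std::min(nb1 - 1, (int)std::floor((b1 - lo1) * bins.inv1));
    int i2a = std::max(0, (int)std::floor((a2 - lo2) * bins.inv2));
    int i2b = std::min(nb2 - 1, (int)std::floor((b2 - lo2) * bins.inv2));
    r1a[tIdx] = i1a; r1b[tIdx] = i1b; r2a[tIdx] = i2a; r2b[tIdx] = i2b;
    for (int j = i2a; j <= i2b; ++j)
      for (int i = i1a; i <= i1b; ++i) cnt[i + nb1 * j + 1]++;
  }
  for (size_t i = 1; i < cnt.size(); ++i) cnt[i] += cnt[i - 1];
  bins.start = cnt;
  bins.tri.assign(cnt.back(), 0);
  std::vector<int> fill(nb1 * nb2, 0);
  for (int tIdx = 0; tIdx < nt; ++tIdx)
    for (int j = r2a[tIdx]; j <= r2b[tIdx]; ++j)
      for (int i = r1a[tIdx]; i <= r1b[tIdx]; ++i) {
        int cidx = i + nb1 * j;
        bins.tri[bins.start[cidx] + fill[cidx]++] = tIdx;
      }
}

// Collect sorted ray-hit distances for one mesh along +axis ray from `o`.
// Returns false if a degenerate hit or odd parity was seen.
static bool column_hits(const NumericMatrix& V, const IntegerMatrix& F,
                        const Bins2D& bins, int axis, const double* o,
                        std::vector<double>& hits, bool require_even = true) {
  hits.clear();
  int ax1 = (axis + 1) % 3, ax2 = (axis + 2) % 3;
  double c1 = o[ax1], c2 = o[ax2];
  int i1 = (int)std::floor((c1 - bins.min1) * bins.inv1);
  int i2 = (int)std::floor((c2 - bins.min2) * bins.inv2);
  if (i1 < 0 || i1 >= bins.nb1 || i2 < 0 || i2 >= bins.nb2) return true;
  double d[3] = {0, 0, 0};
  d[axis] = 1.0;
  int cidx = i1 + bins.nb1 * i2;
  for (int s = bins.start[cidx]; s < bins.start[cidx + 1]; ++s) {
    int tIdx = bins.tri[s];
    double a[3], b[3], c[3], t;
    for (int k = 0; k < 3; ++k) {
      a[k] = V(F(tIdx, 0) - 1, k);
      b[k] = V(F(tIdx, 1) - 1, k);
      c[k] = V(F(tIdx, 2) - 1, k);
    }
    int r = ray_tri(o, d, a, b, c, t);
    if (r < 0) return false;
    if (r > 0 && t > 0) hits.push_back(t);
  }
  if (require_even && hits.size() % 2 != 0) return false;
  std::sort(hits.begin(), hits.end());
  return true;
}

// [[Rcpp::export]]
List cpp_voxelize_links(List linkV, List linkF, IntegerVector n, double dx,
                        NumericVector center, int subres) {
  const int nx = n[0], ny = n[1], nz = n[2];
  const int S1 = nx * subres, S2 = ny * subres, S3 = nz * subres;
  const double h = dx / subres;
  const int nlink = linkV.size();
  const int ss3 = subres * subres * subres;
  const int cs = subres / 2;  // center sub-index (exact center when odd)

  std::vector<unsigned char> inside((size_t)S1 * S2 * S3, 0);
  IntegerVector owner(nx * ny * nz, 0);  // 1-based link owning the center
  int retries = 0, failures = 0;

  std::vector<Bins2D> bins(nlink);
  std::vector<NumericMatrix> Vs;
  std::vector<IntegerMatrix> Fs;
  double blo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double bhi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int l = 0; l < nlink; ++l) {
    Vs.push_back(as<NumericMatrix>(linkV[l]));
    Fs.push_back(as<IntegerMatrix>(linkF[l]));
    for (int i = 0; i < Vs[l].nrow(); ++i)
      for (int a = 0; a < 3; ++a) {
        blo[a] = std::min(blo[a], Vs[l](i, a));
        bhi[a] = std::max(bhi[a], Vs[l](i, a));
      }
    // bin resolution: one bin per subcolumn is ideal but bins are built on
    // the mesh bbox, which is smaller than the domain; cap the count.
    int nb1 = std::min(256, std::max(8, S2));
    int nb2 = std::min(256, std::max(8, S3));
    build_bins(Vs[l], Fs[l], 1, 2, nb1, nb2, bins[l]);
  }
  // sub-index ranges covering the body bbox (pad one cell each side);
  // everything outside is open water and is never touched below
  int lo_s[3], hi_s[3];
  int Sall[3] = {S1, S2, S3};
  for (int a = 0; a < 3; ++a) {
    double flo = (blo[a] - center[a]) / h + 0.5 * Sall[a] - 0.5;
    double fhi = (bhi[a] - center[a]) / h + 0.5 * Sall[a] - 0.5;
    lo_s[a] = std::max(0, (int)std::floor(flo) - subres);
    hi_s[a] = std::min(Sall[a] - 1, (int)std::ceil(fhi) + subres);
  }
  const int clo0 = lo_s[0] / subres, chi0 = hi_s[0] / subres;
  const int clo1 = lo_s[1] / subres, chi1 = hi_s[1] / subres;
  const int clo2 = lo_s[2] / subres, chi2 = hi_s[2] / subres;

  const double x0 = (0.5 - 0.5 * S1) * h + center[0] - 2.0 * dx;  // ray start
  std::vector<double> hits;
  std::vector<std::vector<double>> linkhits(nlink);

  for (int k = lo_s[2]; k <= hi_s[2]; ++k) {
    double zc = (k + 0.5 - 0.5 * S3) * h + center[2];
    for (int j = lo_s[1]; j <= hi_s[1]; ++j) {
      double yc = (j + 0.5 - 0.5 * S2) * h + center[1];
      bool ok = false;
      for (int attempt = 0; attempt < 8 && !ok; ++attempt) {
        double o[3] = {x0, yc, zc + attempt * 7.3e-5 * h};
        ok = true;
        for (int l = 0; l < nlink; ++l) {
          if (!column_hits(Vs[l], Fs[l], bins[l], 0, o, linkhits[l])) {
            ok = false;
            if (attempt > 0) retries++;
            break;
          }
        }
      }
      if (!ok) { failures++; for (int l = 0; l < nlink; ++l) linkhits[l].clear(); }
      for (int l = 0; l < nlink; ++l) {
        const std::vector<double>& hv = linkhits[l];
        for (size_t m = 0; m + 1 < hv.size(); m += 2) {
          // subcells whose center x lies in (x0+hv[m], x0+hv[m+1])
          double xa = x0 + hv[m], xb = x0 + hv[m + 1];
          // x_i = (i + 0.5 - S1/2)*h + center[0]
          double fa = (xa - center[0]) / h + 0.5 * S1 - 0.5;
          double fb = (xb - center[0]) / h + 0.5 * S1 - 0.5;
          int ia = std::max(0, (int)std::floor(fa) + 1);
          int ib = std::min(S1 - 1, (int)std::ceil(fb) - 1);
          for (int i = ia; i <= ib; ++i) {
            size_t sidx = (size_t)i + (size_t)S1 * (j + (size_t)S2 * k);
            inside[sidx] = 1;
            // record the owning link for any cell the link touches; the
            // smallest link index wins so that attribution is independent
            // of traversal order (and hence exactly mirror-symmetric)
            int cell = (i / subres) + nx * ((j / subres) + ny * (k / subres));
            if (owner[cell] == 0 || l + 1 < owner[cell]) owner[cell] = l + 1;
          }
        }
      }
    }
  }

  NumericVector frac(nx * ny * nz, 1.0);
  IntegerVector labels(nx * ny * nz);
  NumericVector wu((nx + 1) * ny * nz, 1.0), wv(nx * (ny + 1) * nz, 1.0),
      ww(nx * ny * (nz + 1), 1.0);
  const double ss2 = (double)(subres * subres);
  // sub-face fluid weight: average of the two adjacent sub-cell indicators
  // (a mixed pair counts half) so that the weighted interface measures the
  // sub-cell voxelized volume without half-cell dilation bias
  auto sub_at = [&](int i, int j, int k) -> int {
    // inside flag of subcell (i,j,k); out-of-domain counts as fluid
    if (i < 0 || i >= S1 || j < 0 || j >= S2 || k < 0 || k >= S3) return 0;
    return inside[(size_t)i + (size_t)S1 * (j + (size_t)S2 * k)];
  };
  // u faces: plane of constant sub-x index fi*subres
  for (int k = clo2; k <= chi2; ++k)
    for (int j = clo1; j <= chi1; ++j)
      for (int fi = clo0; fi <= std::min(nx, chi0 + 1); ++fi) {
        int si = fi * subres;
        int cnt = 0;
        for (int ks = k * subres; ks < (k + 1) * subres; ++ks)
          for (int js = j * subres; js < (j + 1) * subres; ++js)
            cnt += (1 - sub_at(si - 1, js, ks)) + (1 - sub_at(si, js, ks));
        wu[fi + (nx + 1) * (j + ny * k)] = cnt / (2.0 * ss2);
      }
  for (int k = clo2; k <= chi2; ++k)
    for (int fj = clo1; fj <= std::min(ny, chi1 + 1); ++fj)
      for (int i = clo0; i <= chi0; ++i) {
        int sj = fj * subres;
        int cnt = 0;
        for (int ks = k * subres; ks < (k + 1) * subres; ++ks)
          for (int is = i * subres; is < (i + 1) * subres; ++is)
            cnt += (1 - sub_at(is, sj - 1, ks)) + (1 - sub_at(is, sj, ks));
        wv[i + nx * (fj + (ny + 1) * k)] = cnt / (2.0 * ss2);
      }
  for (int fk = clo2; fk <= std::min(nz, chi2 + 1); ++fk)
    for (int j = clo1; j <= chi1; ++j)
      for (int i = clo0; i <= chi0; ++i) {
        int sk = fk * subres;
        int cnt = 0;
        for (int js = j * subres; js < (j + 1) * subres; ++js)
          for (int is = i * subres; is < (i + 1) * subres; ++is)
            cnt += (1 - sub_at(is, js, sk - 1)) + (1 - sub_at(is, js, sk));
        ww[i + nx * (j + ny * fk)] = cnt / (2.0 * ss2);
      }
  for (int ck = clo2; ck <= chi2; ++ck)
    for (int cj = clo1; cj <= chi1; ++cj)
      for (int ci = clo0; ci <= chi0; ++ci) {
        int cnt = 0;
        for (int k = 0; k < subres; ++k)
          for (int j = 0; j < subres; ++j)
            for (int i = 0; i < subres; ++i) {
              size_t sidx = (size_t)(ci * subres + i) +
                (size_t)S1 * ((cj * subres + j) + (size_t)S2 * (ck * subres + k));
              cnt += inside[sidx];
            }
        int cell = ci + nx * (cj + ny * ck);
        frac[cell] = (double)(ss3 - cnt) / ss3;  // fluid fraction
        size_t cc = (size_t)(ci * subres + cs) +
          (size_t)S1 * ((cj * subres + cs) + (size_t)S2 * (ck * subres + cs));
        labels[cell] = inside[cc] ? 1 : 0;
      }

  return List::create(_["labels"] = labels, _["frac"] = frac,
                      _["owner"] = owner, _["wu"] = wu, _["wv"] = wv,
                      _["ww"] = ww, _["retries"] = retries,
                      _["failures"] = failures);
}

// [[Rcpp::export]]
LogicalVector cpp_points_inside(NumericMatrix V, IntegerMatrix F,
                                NumericMatrix P, int axis) {
  int np = P.nrow();
  LogicalVector out(np);
  int ax1 = (axis + 1) % 3, ax2 = (axis + 2) % 3;
  Bins2D bins;
  build_bins(V, F, ax1, ax2, 192, 192, bins);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < V.nrow(); ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], V(i, k));
      hi[k] = std::max(hi[k], V(i, k));
    }
  std::vector<double> hits;
  int nt = F.nrow();
  for (int ip = 0; ip < np; ++ip) {
    double o[3] = {P(ip, 0), P(ip, 1), P(ip, 2)};
    if (o[0] < lo[0] || o[0] > hi[0] || o[1] < lo[1] || o[1] > hi[1] ||
        o[2] < lo[2] || o[2] > hi[2]) {
      out[ip] = false;
      continue;
    }
    if (column_hits(V, F, bins, axis, o, hits, false)) {
      out[ip] = (hits.size() % 2) == 1;
      continue;
    }
    // degenerate: brute force with a deterministic sequence of jittered rays
    bool done = false;
    for (int attempt = 1; attempt <= 8 && !done; ++attempt) {
      double d[3] = {0, 0, 0};
      d[axis] = 1.0;
      d[ax1] = 1.3e-3 * attempt;
      d[ax2] = 0.71e-3 * attempt * attempt;
      int parity = 0;
      bool bad = false;
      for (int tIdx = 0; tIdx < nt && !bad; ++tIdx) {
        double a[3], b[3], c[3], t;
        for (int k = 0; k < 3; ++k) {
          a[k] = V(F(tIdx, 0) - 1, k);
          b[k] = V(F(tIdx, 1) - 1, k);
          c[k] = V(F(tIdx, 2) - 1, k);
        }
        int r = ray_tri(o, d, a, b, c, t);
        if (r < 0) bad = true;
        else if (r > 0 && t > 0) parity++;
      }
      if (!bad) {
        out[ip] = (parity % 2) == 1;
        done = true;
      }
    }
    if (!done) out[ip] = NA_LOGICAL;
  }
  return out;
}
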