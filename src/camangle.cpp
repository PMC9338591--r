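#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Iso-surfacing of a scalar field on a regular grid by marching tetrahedra.
// Each grid cube is split into six tetrahedra sharing the 0-6 body diagonal;
// iso-vertices sit on lattice edges (linear interpolation to `level`) and are
// shared between adjacent tetrahedra through an edge hash, so the mesh is
// watertight and vertex-connected.
// ---------------------------------------------------------------------------

static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
static const int OFF[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};

// [[Rcpp::export(name = ".mt_isosurface")]]
List mt_isosurface(NumericVector field, IntegerVector dims,
                   NumericVector spacing, NumericVector origin, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *f = REAL(field);
  std::unordered_map<uint64_t, int> emap;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  int64_t gidv[8];
  double fv[8];
  int ci[8], cj[8], ck[8];

  for (int k = 0; k < nz - 1; k++) {
    for (int j = 0; j < ny - 1; j++) {
      for (int i = 0; i < nx - 1; i++) {
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; c++) {
          ci[c] = i + OFF[c][0];
          cj[c] = j + OFF[c][1];
          ck[c] = k + OFF[c][2];
          gidv[c] = (int64_t)ci[c] + (int64_t)nx * ((int64_t)cj[c] + (int64_t)ny * ck[c]);
          fv[c] = f[gidv[c]];
          if (fv[c] > level) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;

        for (int t = 0; t < 6; t++) {
          int ins[4], outs[4];
          int ni = 0, no = 0;
          for (int c = 0; c < 4; c++) {
            int v = TETS[t][c];
            if (fv[v] > level) ins[ni++] = v; else outs[no++] = v;
          }
          if (ni == 0 || ni == 4) continue;

          // interpolated vertex on lattice edge (a, b), deduplicated
          auto evtx = [&](int a, int b) -> int {
            uint64_t ga = (uint64_t)gidv[a], gb = (uint64_t)gidv[b];
            uint64_t key = ga < gb ? (ga << 32 | gb) : (gb << 32 | ga);
            auto it = emap.find(key);
            if (it != emap.end()) return it->second;
            double tt = (level - fv[a]) / (fv[b] - fv[a]);
            double px = origin[0] + spacing[0] * (ci[a] + tt * (ci[b] - ci[a]));
            double py = origin[1] + spacing[1] * (cj[a] + tt * (cj[b] - cj[a]));
            double pz = origin[2] + spacing[2] * (ck[a] + tt * (ck[b] - ck[a]));
            int id = (int)vx.size();
            vx.push_back(px); vy.push_back(py); vz.push_back(pz);
            emap[key] = id;
            return id;
          };
          auto pushtri = [&](int a, int b, int c) {
            if (a == b || b == c || a == c) return;
            tri.push_back(a); tri.push_back(b); tri.push_back(c);
          };

          if (ni == 1) {
            pushtri(evtx(ins[0], outs[0]), evtx(ins[0], outs[1]), evtx(ins[0], outs[2]));
          } else if (ni == 3) {
            pushtri(evtx(ins[0], outs[0]), evtx(ins[1], outs[0]), evtx(ins[2], outs[0]));
          } else { // 2 in / 2 out: quad split into two triangles
            int q0 = evtx(ins[0], outs[0]);
            int q1 = evtx(ins[0], outs[1]);
            int q2 = evtx(ins[1], outs[1]);
            int q3 = evtx(ins[1], outs[0]);
            pushtri(q0, q1, q2);
            pushtri(q0, q2, q3);
          }
        }
      }
    }
  }

  int nv = (int)vx.size(), nt = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; v++) { V(v, 0) = vx[v]; V(v, 1) = vy[v]; V(v, 2) = vz[v]; }
  IntegerMatrix F(nt, 3);
  for (int t = 0; t < nt; t++) {
    F(t, 0) = tri[3 * t] + 1;       // 1-based for R
    F(t, 1) = tri[3 * t + 1] + 1;
    F(t, 2) = tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = F);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared), separable lower-envelope
// algorithm, with per-axis sample spacing so anisotropic voxels are handled.
// Input: foreground flags; output: distance (mm) to the nearest background
// voxel centre (0 on background).
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &fbuf, int n, double s,
                 std::vector<double> &d, std::vector<int> &v,
                 std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e30; z[1] = 1e30;
  for (int q = 1; q < n; q++) {
    double xq = q * s;
    double inter;
    while (true) {
      int p = v[k];
      double xp = p * s;
      inter = ((fbuf[q] + xq * xq) - (fbuf[p] + xp * xp)) / (2.0 * (xq - xp));
      if (inter <= z[k]) k--; else break;
    }
    k++;
    v[k] = q;
    z[k] = inter;
    z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double x = q * s;
    while (z[k + 1] < x) k++;
    double dx = x - v[k] * s;
    d[q] = dx * dx + fbuf[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(IntegerVector fg, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> d2(n);
  for (R_xlen_t i = 0; i < n; i++) d2[i] = fg[i] ? 1e20 : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> fbuf(nmax), dbuf(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x lines
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; i++) fbuf[i] = d2[base + i];
      dt1d(fbuf, nx, spacing[0], dbuf, v, z);
      for (int i = 0; i < nx; i++) d2[base + i] = dbuf[i];
    }
  // y lines
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * (R_xlen_t)k;
      for (int j = 0; j < ny; j++) fbuf[j] = d2[base + (R_xlen_t)nx * j];
      dt1d(fbuf, ny, spacing[1], dbuf, v, z);
      for (int j = 0; j < ny; j++) d2[base + (R_xlen_t)nx * j] = dbuf[j];
    }
  // z lines
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; k++) fbuf[k] = d2[base + stride * k];
      dt1d(fbuf, nz, spacing[2], dbuf, v, z);
      for (int k = 0; k < nz; k++) d2[base + stride * k] = dbuf[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(d2[i]);
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected components of a binary volume (iterative flood fill).
// Returns component labels (0 = background) plus component sizes.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".label_components3d")]]
List label_components3d(IntegerVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  std::vector<double> sizes;
  int nextlab = 0;

  for (R_xlen_t s = 0; s < n; s++) {
    if (!occ[s] || lab[s] != 0) continue;
    nextlab++;
    double sz = 0;
    stack.clear();
    stack.push_back(s);
    lab[s] = nextlab;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      sz += 1;
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; dk++) {
        int kk = k + dk; if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; dj++) {
          int jj = j + dj; if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; di++) {
            int ii = i + di; if (ii < 0 || ii >= nx) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (occ[q] && lab[q] == 0) {
              lab[q] = nextlab;
              stack.push_back(q);
            }
          }
        }
      }
    }
    sizes.push_back(sz);
  }
  return List::create(_["labels"] = lab, _["sizes"] = NumericVector(sizes.begin(), sizes.end()));
}

// ---------------------------------------------------------------------------
// Ray casting of a spherical-coordinate direction grid against a triangle
// mesh. Rays start at `center`; direction for cell (theta, phi) is
//   d = sin(theta) (cos(phi) e1 + sin(phi) e2) + cos(theta) e3.
// Triangles are binned by the spherical extents of their vertices (with
// conservative padding near the poles and the phi wrap) so each cell only
// tests nearby triangles; intersection by Moller-Trumbore, keeping the
// smallest positive ray parameter (the first hit).
// theta and phi are in radians and uniformly spaced, phi circular.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".raycast_map")]]
NumericMatrix raycast_map(NumericMatrix V, IntegerMatrix F, NumericVector center,
                          NumericVector e1, NumericVector e2, NumericVector e3,
                          NumericVector theta, NumericVector phi) {
  const int nt = theta.size(), np = phi.size();
  const int nv = V.nrow(), nf = F.nrow();
  const double dth = nt > 1 ? theta[1] - theta[0] : M_PI;
  const double dph = np > 1 ? phi[1] - phi[0] : 2 * M_PI;

  // precompute direction vectors per cell
  std::vector<double> dirx((size_t)nt * np), diry((size_t)nt * np), dirz((size_t)nt * np);
  for (int ip = 0; ip < np; ip++) {
    double cp = std::cos(phi[ip]), sp = std::sin(phi[ip]);
    double ux = cp * e1[0] + sp * e2[0];
    double uy = cp * e1[1] + sp * e2[1];
    double uz = cp * e1[2] + sp * e2[2];
    for (int it = 0; it < nt; it++) {
      double st = std::sin(theta[it]), ct = std::cos(theta[it]);
      size_t id = (size_t)it + (size_t)nt * ip;
      dirx[id] = st * ux + ct * e3[0];
      diry[id] = st * uy + ct * e3[1];
      dirz[id] = st * uz + ct * e3[2];
    }
  }

  // vertex spherical coordinates relative to center
  std::vector<double> vth(nv), vph(nv), rx(nv), ry(nv), rz(nv), rn(nv);
  for (int v = 0; v < nv; v++) {
    double dx = V(v, 0) - center[0], dy = V(v, 1) - center[1], dz = V(v, 2) - center[2];
    rx[v] = dx; ry[v] = dy; rz[v] = dz;
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    rn[v] = r;
    double a3 = (dx * e3[0] + dy * e3[1] + dz * e3[2]) / (r > 0 ? r : 1);
    a3 = std::max(-1.0, std::min(1.0, a3));
    vth[v] = std::acos(a3);
    double a1 = dx * e1[0] + dy * e1[1] + dz * e1[2];
    double a2 = dx * e2[0] + dy * e2[1] + dz * e2[2];
    double p = std::atan2(a2, a1);
    if (p < 0) p += 2 * M_PI;
    vph[v] = p;
  }

  NumericMatrix out(nt, np);
  std::fill(out.begin(), out.end(), NA_REAL);

  const double TWO_PI = 2 * M_PI;
  for (int t = 0; t < nf; t++) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    // angular diameter of the triangle as seen from the center
    double diam = 0;
    int vs[3] = {a, b, c};
    for (int u = 0; u < 3; u++)
      for (int w = u + 1; w < 3; w++) {
        int p = vs[u], q = vs[w];
        double dot = (rx[p] * rx[q] + ry[p] * ry[q] + rz[p] * rz[q]) /
                     ((rn[p] > 0 ? rn[p] : 1) * (rn[q] > 0 ? rn[q] : 1));
        dot = std::max(-1.0, std::min(1.0, dot));
        double ang = std::acos(dot);
        if (ang > diam) diam = ang;
      }

    double thmin = std::min(vth[a], std::min(vth[b], vth[c]));
    double thmax = std::max(vth[a], std::max(vth[b], vth[c]));
    double padt = dth + 0.6 * diam;
    double lo = thmin - padt, hi = thmax + padt;
    int it0 = (int)std::floor((lo - theta[0]) / dth);
    int it1 = (int)std::ceil((hi - theta[0]) / dth);
    if (it0 < 0) it0 = 0;
    if (it1 > nt - 1) it1 = nt - 1;
    if (it0 > it1) continue;

    // phi range, unwrapped around the first vertex
    double p0 = vph[a];
    double p1 = vph[b], p2 = vph[c];
    if (p1 - p0 > M_PI) p1 -= TWO_PI; else if (p0 - p1 > M_PI) p1 += TWO_PI;
    if (p2 - p0 > M_PI) p2 -= TWO_PI; else if (p0 - p2 > M_PI) p2 += TWO_PI;
    double pmin = std::min(p0, std::min(p1, p2));
    double pmax = std::max(p0, std::max(p1, p2));
    double sth = std::sin(std::max(0.05, thmin - padt > 0 ? thmin - padt : 0.05));
    double padp = dph + 0.8 * diam / sth;
    bool fullphi = (thmin - padt) < 0.0 || (thmax + padt) > M_PI ||
                   (pmax - pmin) > 2.5 || (pmax - pmin + 2 * padp) >= TWO_PI;

    int ip0 = 0, ipn = np;
    if (!fullphi) {
      ip0 = (int)std::floor((pmin - padp - phi[0]) / dph);
      int ip1 = (int)std::ceil((pmax + padp - phi[0]) / dph);
      ipn = ip1 - ip0 + 1;
      if (ipn > np) { ip0 = 0; ipn = np; }
    }

    // Moller-Trumbore setup
    double e1x = rx[b] - rx[a], e1y = ry[b] - ry[a], e1z = rz[b] - rz[a];
    double e2x = rx[c] - rx[a], e2y = ry[c] - ry[a], e2z = rz[c] - rz[a];

    for (int q = 0; q < ipn; q++) {
      int ip = ((ip0 + q) % np + np) % np;
      for (int it = it0; it <= it1; it++) {
        size_t id = (size_t)it + (size_t)nt * ip;
        double dx = dirx[id], dy = diry[id], dz = dirz[id];
        double hx = dy * e2z - dz * e2y;
        double hy = dz * e2x - dx * e2z;
        double hz = dx * e2y - dy * e2x;
        double det = e1x * hx + e1y * hy + e1z * hz;
        if (std::fabs(det) < 1e-12) continue;
        double inv = 1.0 / det;
        double sx = -rx[a], sy = -ry[a], sz = -rz[a];
        double uu = (sx * hx + sy * hy + sz * hz) * inv;
        if (uu < -1e-9 || uu > 1 + 1e-9) continue;
        double qx = sy * e1z - sz * e1y;
        double qy = sz * e1x - sx * e1z;
        double qz = sx * e1y - sy * e1x;
        double vv = (dx * qx + dy * qy + dz * qz) * inv;
        if (vv < -1e-9 || uu + vv > 1 + 1e-9) continue;
        double tt = (e2x * qx + e2y * qy + e2z * qz) * inv;
        if (tt <= 1e-9) continue;
        double curr = out(it, ip);
        if (ISNA(curr) || tt < curr) out(it, ip) = tt;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Optimal horizontal cut through a cost grid D (n_theta x n_phi) with an L1
// smoothness penalty lambda * |cut(p+1) - cut(p)| over a CIRCULAR phi domain.
// Solved exactly: a forward dynamic programme (with O(n) L1 distance
// transforms) is run once per possible starting state; the circular closure
// term lambda * |end - start| is added at the end. Ties broken toward the
// lowest theta index, so at lambda = 0 the result equals independent
// per-column first-minimum search.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".dp_cut")]]
List dp_cut(NumericMatrix D, double lambda) {
  const int nt = D.nrow(), np = D.ncol();
  IntegerVector best_path(np);
  double best_cost = R_PosInf;

  if (np == 1) {
    int bi = 0;
    for (int i = 1; i < nt; i++) if (D(i, 0) < D(bi, 0)) bi = i;
    best_path[0] = bi + 1;
    return List::create(_["path"] = best_path, _["cost"] = D(bi, 0));
  }

  std::vector<double> dp(nt), m(nt);
  std::vector<int> arg(nt);
  std::vector<int> pred((size_t)nt * np);
  std::vector<int> cur_path(np);

  for (int s = 0; s < nt; s++) {
    for (int i = 0; i < nt; i++) dp[i] = 1e300;
    dp[s] = D(s, 0);
    for (int p = 1; p < np; p++) {
      m[0] = dp[0]; arg[0] = 0;
      for (int i = 1; i < nt; i++) {
        double carried = m[i - 1] + lambda;
        if (dp[i] < carried) { m[i] = dp[i]; arg[i] = i; }
        else { m[i] = carried; arg[i] = arg[i - 1]; }
      }
      for (int i = nt - 2; i >= 0; i--) {
        double carried = m[i + 1] + lambda;
        if (carried < m[i]) { m[i] = carried; arg[i] = arg[i + 1]; }
      }
      for (int i = 0; i < nt; i++) {
        dp[i] = m[i] + D(i, p);
        pred[(size_t)i + (size_t)nt * p] = arg[i];
      }
    }
    // circular closure back to the start state
    int jbest = 0;
    double cbest = dp[0] + lambda * std::abs(0 - s);
    for (int j = 1; j < nt; j++) {
      double tot = dp[j] + lambda * std::abs(j - s);
      if (tot < cbest) { cbest = tot; jbest = j; }
    }
    if (cbest < best_cost) {
      best_cost = cbest;
      cur_path[np - 1] = jbest;
      for (int p = np - 1; p >= 1; p--)
        cur_path[p - 1] = pred[(size_t)cur_path[p] + (size_t)nt * p];
      for (int p = 0; p < np; p++) best_path[p] = cur_path[p] + 1;
    }
  }
  return List::create(_["path"] = best_path, _["cost"] = best_cost);
}
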