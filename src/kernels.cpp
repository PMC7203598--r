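#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 3D connected-component labelling, BFS. conn = 1 (face), 2 (edge) or
// 3 (vertex) neighbourhoods. Returns integer labels, 0 = background,
// components numbered from 1.
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims, int conn) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0 || m > conn) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  const int nd = (int)dx.size();
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t c = q.front(); q.pop();
      int k = (int)(c / ((R_xlen_t)nx * ny));
      int r = (int)(c % ((R_xlen_t)nx * ny));
      int j = r / nx, i = r % nx;
      for (int d = 0; d < nd; ++d) {
        int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t t = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[t] && lab[t] == 0) { lab[t] = next; q.push(t); }
      }
    }
  }
  lab.attr("ncomp") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Slice-wise exterior flood fill. Per z-slice, background voxels reachable
// from the slice border through face-connected (2D) background are exterior.
// Returns 0 = bone, 1 = exterior background, 2 = enclosed background.
// [[Rcpp::export(name = ".flood_exterior_slices")]]
IntegerVector flood_exterior_slices(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  std::vector<char> vis((size_t)nx * ny);
  std::queue<int> q;
  const int dx[4] = {1, -1, 0, 0};
  const int dy[4] = {0, 0, 1, -1};
  for (int k = 0; k < nz; ++k) {
    R_xlen_t off = (R_xlen_t)nx * ny * k;
    std::fill(vis.begin(), vis.end(), 0);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && i != nx - 1 && j != 0 && j != ny - 1) continue;
        int s = i + nx * j;
        if (!mask[off + s] && !vis[s]) { vis[s] = 1; q.push(s); }
      }
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int j = c / nx, i = c % nx;
      for (int d = 0; d < 4; ++d) {
        int ii = i + dx[d], jj = j + dy[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
        int t = ii + nx * jj;
        if (!mask[off + t] && !vis[t]) { vis[t] = 1; q.push(t); }
      }
    }
    for (int s = 0; s < nx * ny; ++s)
      out[off + s] = mask[off + s] ? 0 : (vis[s] ? 1 : 2);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur with reflective boundaries; kernel truncated at 3
// sigma. sigma in voxels; sigma <= 0 returns the input unchanged.
// [[Rcpp::export(name = ".blur3d")]]
NumericVector blur3d(NumericVector arr, IntegerVector dims, double sigma) {
  if (sigma <= 0) return clone(arr);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double ksum = 0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    ksum += ker[t + rad];
  }
  for (double &v : ker) v /= ksum;
  NumericVector a = clone(arr);
  NumericVector b(a.size());
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const int len = n[ax];
    const R_xlen_t st = stride[ax];
    // iterate over all lines along axis ax
    for (int k = 0; k < (ax == 2 ? 1 : nz); ++k)
      for (int j = 0; j < (ax == 1 ? 1 : ny); ++j)
        for (int i = 0; i < (ax == 0 ? 1 : nx); ++i) {
          R_xlen_t base = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          for (int p = 0; p < len; ++p) {
            double acc = 0;
            for (int t = -rad; t <= rad; ++t) {
              int pp = p + t;
              if (pp < 0) pp = -pp - 1;            // reflect
              if (pp >= len) pp = 2 * len - pp - 1;
              if (pp < 0) pp = 0;                  // very short axes
              if (pp >= len) pp = len - 1;
              acc += ker[t + rad] * a[base + (R_xlen_t)pp * st];
            }
            b[base + (R_xlen_t)p * st] = acc;
          }
        }
    std::swap(a, b);
  }
  return a;
}

// ---------------------------------------------------------------------------
// Surface nodes on the (nx+1) x (ny+1) x (nz+1) node lattice: nodes incident
// to at least one exposed element face (face whose neighbouring voxel is not
// bone or lies outside the grid).
// [[Rcpp::export(name = ".surface_node_grid")]]
LogicalVector surface_node_grid(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx + 1, my = ny + 1, mz = nz + 1;
  LogicalVector out((R_xlen_t)mx * my * mz, false);
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)]) continue;
        for (int d = 0; d < 6; ++d) {
          int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
          bool nb = (ii >= 0 && ii < nx && jj >= 0 && jj < ny &&
                     kk >= 0 && kk < nz) &&
                    mask[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          if (nb) continue;
          // mark the 4 nodes of the exposed face
          for (int b = 0; b < 4; ++b) {
            int ni, nj, nk;
            int u = b & 1, v = (b >> 1) & 1;
            if (d < 2) {        // +/- x face
              ni = i + (d == 0 ? 1 : 0); nj = j + u; nk = k + v;
            } else if (d < 4) { // +/- y face
              nj = j + (d == 2 ? 1 : 0); ni = i + u; nk = k + v;
            } else {            // +/- z face
              nk = k + (d == 4 ? 1 : 0); ni = i + u; nj = j + v;
            }
            out[ni + (R_xlen_t)mx * (nj + (R_xlen_t)my * nk)] = true;
          }
        }
      }
  return out;
}

// ---------------------------------------------------------------------------
// Hexahedral element machinery. Local node ordering (natural coords):
//   0:(-,-,-) 1:(+,-,-) 2:(+,+,-) 3:(-,+,-) 4:(-,-,+) 5:(+,-,+) 6:(+,+,+)
//   7:(-,+,+)
static const double SGN[8][3] = {
  {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
  {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1}};

// isotropic elasticity matrix (engineering shear strains)
static void dmat(double E, double nu, double D[6][6]) {
  double lam = E * nu / ((1 + nu) * (1 - 2 * nu));
  double mu = E / (2 * (1 + nu));
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) D[a][b] = 0;
  for (int a = 0; a < 3; ++a) {
    for (int b = 0; b < 3; ++b) D[a][b] = lam;
    D[a][a] = lam + 2 * mu;
    D[a + 3][a + 3] = mu;
  }
}

// B matrix (6 x 24) at natural coordinates (xi, eta, zeta) for a cube of
// edge h; engineering shear convention.
static void bmat(double xi, double eta, double zeta, double h, double B[6][24]) {
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 24; ++b) B[a][b] = 0;
  double s = 2.0 / h; // d(natural)/d(physical)
  for (int a = 0; a < 8; ++a) {
    double gx = 0.125 * SGN[a][0] * (1 + SGN[a][1] * eta) * (1 + SGN[a][2] * zeta) * s;
    double gy = 0.125 * SGN[a][1] * (1 + SGN[a][0] * xi) * (1 + SGN[a][2] * zeta) * s;
    double gz = 0.125 * SGN[a][2] * (1 + SGN[a][0] * xi) * (1 + SGN[a][1] * eta) * s;
    B[0][3 * a] = gx;
    B[1][3 * a + 1] = gy;
    B[2][3 * a + 2] = gz;
    B[3][3 * a] = gy; B[3][3 * a + 1] = gx;       // gamma_xy
    B[4][3 * a + 1] = gz; B[4][3 * a + 2] = gy;   // gamma_yz
    B[5][3 * a] = gz; B[5][3 * a + 2] = gx;       // gamma_zx
  }
}

// Element stiffness matrix for a cube voxel of edge h (m), 2x2x2 Gauss.
// [[Rcpp::export(name = ".hex_ke")]]
NumericMatrix hex_ke(double h, double E, double nu) {
  NumericMatrix ke(24, 24);
  double D[6][6], B[6][24];
  dmat(E, nu, D);
  double g = 1.0 / std::sqrt(3.0);
  double w = (h / 2) * (h / 2) * (h / 2); // det J, unit gauss weights
  for (int p = 0; p < 8; ++p) {
    bmat(g * SGN[p][0], g * SGN[p][1], g * SGN[p][2], h, B);
    double DB[6][24];
    for (int a = 0; a < 6; ++a)
      for (int b = 0; b < 24; ++b) {
        double acc = 0;
        for (int c = 0; c < 6; ++c) acc += D[a][c] * B[c][b];
        DB[a][b] = acc;
      }
    for (int a = 0; a < 24; ++a)
      for (int b = 0; b < 24; ++b) {
        double acc = 0;
        for (int c = 0; c < 6; ++c) acc += B[c][a] * DB[c][b];
        ke(a, b) += w * acc;
      }
  }
  return ke;
}

// ---------------------------------------------------------------------------
// Matrix-free preconditioned conjugate gradient solve of the reduced system.
// node_type: 0 free, 1 fixed (proximal), 2 coupled to the distal master.
// The three master translations are reduced DOFs 0..2; each free node carries
// three DOFs. The load enters at the master (reference point).
struct Reduction {
  int nn, nred, nmaster;
  std::vector<int> base; // per node: -1 fixed, -2 master, else first DOF index
};

static Reduction make_reduction(const IntegerVector &node_type) {
  Reduction rd;
  rd.nn = node_type.size();
  rd.base.resize(rd.nn);
  rd.nmaster = 0;
  for (int i = 0; i < rd.nn; ++i)
    if (node_type[i] == 2) rd.nmaster++;
  int idx = rd.nmaster > 0 ? 3 : 0;
  for (int i = 0; i < rd.nn; ++i) {
    if (node_type[i] == 1) rd.base[i] = -1;
    else if (node_type[i] == 2) rd.base[i] = -2;
    else { rd.base[i] = idx; idx += 3; }
  }
  rd.nred = idx;
  return rd;
}

static void expand(const Reduction &rd, const std::vector<double> &x,
                   std::vector<double> &ufull) {
  for (int i = 0; i < rd.nn; ++i) {
    int b = rd.base[i];
    for (int c = 0; c < 3; ++c) {
      double v = 0;
      if (b >= 0) v = x[b + c];
      else if (b == -2) v = x[c];
      ufull[3 * i + c] = v;
    }
  }
}

static void contract(const Reduction &rd, const std::vector<double> &yfull,
                     std::vector<double> &y) {
  std::fill(y.begin(), y.end(), 0.0);
  for (int i = 0; i < rd.nn; ++i) {
    int b = rd.base[i];
    for (int c = 0; c < 3; ++c) {
      if (b >= 0) y[b + c] = yfull[3 * i + c];
      else if (b == -2) y[c] += yfull[3 * i + c];
    }
  }
}

static void kmul(const IntegerMatrix &elems, const NumericMatrix &ke,
                 const std::vector<double> &ufull, std::vector<double> &yfull) {
  std::fill(yfull.begin(), yfull.end(), 0.0);
  const int ne = elems.nrow();
  double ue[24], ye[24];
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a);
      ue[3 * a] = ufull[3 * n];
      ue[3 * a + 1] = ufull[3 * n + 1];
      ue[3 * a + 2] = ufull[3 * n + 2];
    }
    for (int a = 0; a < 24; ++a) {
      double acc = 0;
      for (int b = 0; b < 24; ++b) acc += ke(a, b) * ue[b];
      ye[a] = acc;
    }
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a);
      yfull[3 * n] += ye[3 * a];
      yfull[3 * n + 1] += ye[3 * a + 1];
      yfull[3 * n + 2] += ye[3 * a + 2];
    }
  }
}

// [[Rcpp::export(name = ".fe_solve")]]
List fe_solve(IntegerMatrix elems, IntegerVector node_type, NumericMatrix ke,
              NumericVector f_master, double tol, int maxit) {
  Reduction rd = make_reduction(node_type);
  const int nn = rd.nn, nred = rd.nred, ne = elems.nrow();
  if (rd.nmaster == 0) stop("no coupled (distal) nodes in the model");
  std::vector<double> ufull(3 * nn), yfull(3 * nn);
  // reduced diagonal for the Jacobi preconditioner
  std::vector<double> diag(nred, 0.0);
  {
    std::vector<double> dfull(3 * nn, 0.0);
    for (int e = 0; e < ne; ++e)
      for (int a = 0; a < 8; ++a) {
        int n = elems(e, a);
        for (int c = 0; c < 3; ++c) dfull[3 * n + c] += ke(3 * a + c, 3 * a + c);
      }
    contract(rd, dfull, diag);
  }
  // right-hand side: load at the master translations only
  std::vector<double> b(nred, 0.0), x(nred, 0.0), r(nred), z(nred), p(nred),
      ap(nred);
  for (int c = 0; c < 3; ++c) b[c] = f_master[c];
  double bnorm = 0;
  for (int i = 0; i < nred; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0) {
    NumericMatrix u(nn, 3);
    return List::create(_["u"] = u, _["iters"] = 0, _["relres"] = 0.0,
                        _["converged"] = true);
  }
  r = b;
  for (int i = 0; i < nred; ++i) z[i] = r[i] / diag[i];
  p = z;
  double rz = 0;
  for (int i = 0; i < nred; ++i) rz += r[i] * z[i];
  int it = 0;
  double relres = 1.0;
  for (it = 1; it <= maxit; ++it) {
    expand(rd, p, ufull);
    kmul(elems, ke, ufull, yfull);
    contract(rd, yfull, ap);
    double pap = 0;
    for (int i = 0; i < nred; ++i) pap += p[i] * ap[i];
    if (pap <= 0) stop("system not positive definite (pAp <= 0)");
    double alpha = rz / pap;
    double rn = 0;
    for (int i = 0; i < nred; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * ap[i];
      rn += r[i] * r[i];
    }
    relres = std::sqrt(rn) / bnorm;
    if (relres <= tol) break;
    double rznew = 0;
    for (int i = 0; i < nred; ++i) {
      z[i] = r[i] / diag[i];
      rznew += r[i] * z[i];
    }
    double beta = rznew / rz;
    rz = rznew;
    for (int i = 0; i < nred; ++i) p[i] = z[i] + beta * p[i];
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }
  bool conv = relres <= tol;
  expand(rd, x, ufull);
  NumericMatrix u(nn, 3);
  for (int i = 0; i < nn; ++i)
    for (int c = 0; c < 3; ++c) u(i, c) = ufull[3 * i + c];
  return List::create(_["u"] = u, _["iters"] = std::min(it, maxit),
                      _["relres"] = relres, _["converged"] = conv);
}

// Action of the global stiffness on an unconstrained full nodal vector
// (used by symmetry / rigid-body property checks).
// [[Rcpp::export(name = ".k_apply")]]
NumericMatrix k_apply(IntegerMatrix elems, int nn, NumericMatrix ke,
                      NumericMatrix u) {
  std::vector<double> ufull(3 * nn), yfull(3 * nn);
  for (int i = 0; i < nn; ++i)
    for (int c = 0; c < 3; ++c) ufull[3 * i + c] = u(i, c);
  kmul(elems, ke, ufull, yfull);
  NumericMatrix y(nn, 3);
  for (int i = 0; i < nn; ++i)
    for (int c = 0; c < 3; ++c) y(i, c) = yfull[3 * i + c];
  return y;
}

// largest eigenvalue of a symmetric 3x3 tensor (analytic, trigonometric)
static double max_eig_sym3(double xx, double yy, double zz, double xy,
                           double yz, double zx) {
  double p1 = xy * xy + yz * yz + zx * zx;
  if (p1 < 1e-300) return std::max(xx, std::max(yy, zz));
  double q = (xx + yy + zz) / 3.0;
  double p2 = (xx - q) * (xx - q) + (yy - q) * (yy - q) + (zz - q) * (zz - q) +
              2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  // B = (A - q I) / p ; r = det(B) / 2
  double bxx = (xx - q) / p, byy = (yy - q) / p, bzz = (zz - q) / p;
  double bxy = xy / p, byz = yz / p, bzx = zx / p;
  double r = (bxx * (byy * bzz - byz * byz) - bxy * (bxy * bzz - byz * bzx) +
              bzx * (bxy * byz - byy * bzx)) / 2.0;
  r = std::max(-1.0, std::min(1.0, r));
  double phi = std::acos(r) / 3.0;
  return q + 2.0 * p * std::cos(phi);
}

// ---------------------------------------------------------------------------
// Nodal stimulus. Strains at 2x2x2 Gauss points are extrapolated to element
// corners by the standard trilinear rule and averaged over elements sharing
// each node. kind 0 = SED (Pa); kind 1 = maximum principal strain (unitless).
// For SED the scalar is extrapolated; for the principal strain the six tensor
// components are extrapolated/averaged first, the eigenvalue taken last.
// [[Rcpp::export(name = ".stimulus_nodal")]]
List stimulus_nodal(IntegerMatrix elems, NumericMatrix u, int nn, double h,
                    double E, double nu, int kind) {
  const int ne = elems.nrow();
  double D[6][6];
  dmat(E, nu, D);
  double g = 1.0 / std::sqrt(3.0), s3 = std::sqrt(3.0);
  // B matrices at the 8 gauss points
  double Bg[8][6][24];
  for (int p = 0; p < 8; ++p)
    bmat(g * SGN[p][0], g * SGN[p][1], g * SGN[p][2], h, Bg[p]);
  // extrapolation matrix: corner a <- gauss p
  double Ex[8][8];
  for (int a = 0; a < 8; ++a)
    for (int p = 0; p < 8; ++p)
      Ex[a][p] = 0.125 * (1 + SGN[p][0] * SGN[a][0] * s3) *
                 (1 + SGN[p][1] * SGN[a][1] * s3) *
                 (1 + SGN[p][2] * SGN[a][2] * s3);
  int ncomp = (kind == 0) ? 1 : 6;
  std::vector<double> acc((size_t)nn * ncomp, 0.0);
  std::vector<int> cnt(nn, 0);
  double ue[24], eps[8][6], val[8];
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a);
      ue[3 * a] = u(n, 0);
      ue[3 * a + 1] = u(n, 1);
      ue[3 * a + 2] = u(n, 2);
    }
    for (int p = 0; p < 8; ++p)
      for (int c = 0; c < 6; ++c) {
        double a2 = 0;
        for (int b = 0; b < 24; ++b) a2 += Bg[p][c][b] * ue[b];
        eps[p][c] = a2;
      }
    if (kind == 0) {
      for (int p = 0; p < 8; ++p) {
        double sed = 0;
        for (int a = 0; a < 6; ++a) {
          double sg = 0;
          for (int b = 0; b < 6; ++b) sg += D[a][b] * eps[p][b];
          sed += sg * eps[p][a];
        }
        val[p] = 0.5 * sed;
      }
      for (int a = 0; a < 8; ++a) {
        double v = 0;
        for (int p = 0; p < 8; ++p) v += Ex[a][p] * val[p];
        int n = elems(e, a);
        acc[n] += v;
      }
    } else {
      for (int a = 0; a < 8; ++a) {
        int n = elems(e, a);
        for (int c = 0; c < 6; ++c) {
          double v = 0;
          for (int p = 0; p < 8; ++p) v += Ex[a][p] * eps[p][c];
          acc[(size_t)n * 6 + c] += v;
        }
      }
    }
    for (int a = 0; a < 8; ++a) cnt[elems(e, a)]++;
  }
  NumericVector out(nn);
  for (int n = 0; n < nn; ++n) {
    if (cnt[n] == 0) { out[n] = NA_REAL; continue; }
    if (kind == 0) {
      out[n] = acc[n] / cnt[n];
    } else {
      double exx = acc[(size_t)n * 6] / cnt[n];
      double eyy = acc[(size_t)n * 6 + 1] / cnt[n];
      double ezz = acc[(size_t)n * 6 + 2] / cnt[n];
      // engineering shears -> tensor shears
      double exy = acc[(size_t)n * 6 + 3] / cnt[n] / 2.0;
      double eyz = acc[(size_t)n * 6 + 4] / cnt[n] / 2.0;
      double ezx = acc[(size_t)n * 6 + 5] / cnt[n] / 2.0;
      out[n] = max_eig_sym3(exx, eyy, ezz, exy, eyz, ezx);
    }
  }
  return List::create(_["value"] = out, _["count"] = wrap(cnt));
}

// ---------------------------------------------------------------------------
// BRU density update. Each surface node (lattice coords, 0-based: node
// (i,j,k) touches voxels (i-1..i, j-1..j, k-1..k)) proposes new TMD values
// for its incident voxels: the 8-voxel mean is driven to mean + delta by one
// multiplicative factor applied to the direction-dependent scaled set
// (apposition: background + TZ; resorption: bone + TZ; roles 0/1/2).
// Proposals are averaged per voxel; the kernel accumulates proposal minus
// current value so that untouched BRUs leave voxels bit-identical. Returns
// the per-voxel sums of proposal deltas, proposal counts, and the number of
// saturated BRUs (empty scaled set or scaling factor floored at zero).
// [[Rcpp::export(name = ".bru_update")]]
List bru_update_kernel(NumericVector tmd, IntegerVector dims,
                       IntegerVector roles, IntegerMatrix node_ijk,
                       NumericVector delta, double floor_val) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector dsum(nvox, 0.0);
  IntegerVector propcount(nvox, 0);
  int nsat = 0;
  const int ns = node_ijk.nrow();
  R_xlen_t vox[8];
  double vals[8], v0[8];
  int rol[8];
  for (int s = 0; s < ns; ++s) {
    int i = node_ijk(s, 0), j = node_ijk(s, 1), k = node_ijk(s, 2);
    int m = 0;
    for (int dk = -1; dk <= 0; ++dk)
      for (int dj = -1; dj <= 0; ++dj)
        for (int di = -1; di <= 0; ++di) {
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          R_xlen_t v = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          vox[m] = v;
          vals[m] = tmd[v];
          v0[m] = tmd[v];
          rol[m] = roles[v];
          ++m;
        }
    if (m == 0) continue;
    double d = delta[s];
    double mean0 = 0;
    for (int a = 0; a < m; ++a) mean0 += vals[a];
    mean0 /= m;
    double prop[8];
    for (int a = 0; a < m; ++a) prop[a] = vals[a];
    if (d != 0) {
      bool scale_bg = d > 0; // apposition scales background + TZ
      double sumS = 0, sumO = 0;
      bool inS[8];
      for (int a = 0; a < m; ++a) {
        inS[a] = scale_bg ? (rol[a] != 2) : (rol[a] != 0);
        if (inS[a]) {
          if (vals[a] < floor_val) vals[a] = floor_val;
          sumS += vals[a];
        } else {
          sumO += vals[a];
        }
      }
      if (sumS <= 0) {
        ++nsat;
      } else {
        double c = (m * (mean0 + d) - sumO) / sumS;
        if (c < 0) { c = 0; ++nsat; }
        for (int a = 0; a < m; ++a)
          if (inS[a]) prop[a] = c * vals[a];
      }
    }
    for (int a = 0; a < m; ++a) {
      dsum[vox[a]] += prop[a] - v0[a];
      propcount[vox[a]] += 1;
    }
  }
  return List::create(_["dsum"] = dsum, _["propcount"] = propcount,
                      _["saturated"] = nsat);
}
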