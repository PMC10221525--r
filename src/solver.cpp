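// Two-dimensional incompressible two-phase solver.
//
// Staggered (MAC) layout: scalars phi, p at cell centres (nx x ny),
// u at vertical faces ((nx+1) x ny), v at horizontal faces (nx x (ny+1)).
// Column-major indexing matches R matrices: cell (i,j) -> i + j*nx.
//
// Time step: explicit upwind advection of momentum and of the conservative
// level-set field, implicit variable-viscosity Laplacian (the small
// transpose-stress remainder is explicit), balanced-force continuum-surface
// -force surface tension, Chorin projection with a variable-coefficient
// pressure Poisson equation solved by warm-started Jacobi-preconditioned CG.
//
// Face tag codes (shared with R): 0 none, 1 wall, 2 continuous inlet,
// 3 dispersed inlet, 4 outlet.

#include <Rcpp.h>
#include <chrono>
#include <vector>
#include <cmath>
#include <cstdint>
#include <functional>

using namespace Rcpp;

static const int TAG_NONE = 0, TAG_WALL = 1, TAG_INC = 2, TAG_IND = 3,
                 TAG_OUT = 4;

struct Grid {
  int nx, ny;
  double h;                       // metres
  std::vector<uint8_t> fluid;     // nx*ny
  std::vector<int> xtag;          // (nx+1)*ny
  std::vector<int> ytag;          // nx*(ny+1)
  inline int C(int i, int j) const { return i + j * nx; }
  inline int FX(int i, int j) const { return i + j * (nx + 1); }
  inline int FY(int i, int j) const { return i + j * nx; }
  inline bool fl(int i, int j) const {
    return i >= 0 && i < nx && j >= 0 && j < ny && fluid[C(i, j)];
  }
};

// u-face classification: 0 inactive, 1 interior (unknown), 2 Dirichlet,
// 3 outlet
struct FaceInfo {
  std::vector<uint8_t> ukind, vkind;
  std::vector<double> ubc, vbc;   // Dirichlet values (inlet profile / wall 0)
};

static void classify_faces(const Grid& g, double u_c, double u_d,
                           FaceInfo& f) {
  int nx = g.nx, ny = g.ny;
  f.ukind.assign((nx + 1) * ny, 0);
  f.ubc.assign((nx + 1) * ny, 0.0);
  f.vkind.assign(nx * (ny + 1), 0);
  f.vbc.assign(nx * (ny + 1), 0.0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i <= nx; ++i) {
      bool L = g.fl(i - 1, j), R = g.fl(i, j);
      int t = g.xtag[g.FX(i, j)];
      int id = g.FX(i, j);
      if (L && R) f.ukind[id] = 1;
      else if (L || R) {
        if (t == TAG_OUT) f.ukind[id] = 3;
        else f.ukind[id] = 2;   // wall or inlet; value set below
      }
    }
  for (int j = 0; j <= ny; ++j)
    for (int i = 0; i < nx; ++i) {
      bool B = g.fl(i, j - 1), T = g.fl(i, j);
      int t = g.ytag[g.FY(i, j)];
      int id = g.FY(i, j);
      if (B && T) f.vkind[id] = 1;
      else if (B || T) {
        if (t == TAG_OUT) f.vkind[id] = 3;
        else f.vkind[id] = 2;
      }
    }
  // parabolic inlet profiles over contiguous runs of inlet faces
  for (int i = 0; i <= nx; ++i) {
    int j = 0;
    while (j < ny) {
      int t = g.xtag[g.FX(i, j)];
      if ((t == TAG_INC || t == TAG_IND) && f.ukind[g.FX(i, j)] == 2) {
        int j0 = j;
        while (j < ny && g.xtag[g.FX(i, j)] == t &&
               f.ukind[g.FX(i, j)] == 2) ++j;
        int n = j - j0;
        double mean = (t == TAG_INC) ? u_c : u_d;
        double sgn = g.fl(i, j0) ? 1.0 : -1.0;  // inflow toward fluid side
        double ssum = 0;
        for (int k = 0; k < n; ++k) {
          double s = (k + 0.5) / n * 2.0 - 1.0;     // -1..1 across the run
          ssum += 1.0 - s * s;
        }
        double scale = mean * n / ssum;  // discrete mean exactly `mean`
        for (int k = 0; k < n; ++k) {
          double s = (k + 0.5) / n * 2.0 - 1.0;
          f.ubc[g.FX(i, j0 + k)] = sgn * scale * (1.0 - s * s);
        }
      } else ++j;
    }
  }
  for (int j = 0; j <= ny; ++j) {
    int i = 0;
    while (i < nx) {
      int t = g.ytag[g.FY(i, j)];
      if ((t == TAG_INC || t == TAG_IND) && f.vkind[g.FY(i, j)] == 2) {
        int i0 = i;
        while (i < nx && g.ytag[g.FY(i, j)] == t &&
               f.vkind[g.FY(i, j)] == 2) ++i;
        int n = i - i0;
        double mean = (t == TAG_INC) ? u_c : u_d;
        double sgn = g.fl(i0, j) ? 1.0 : -1.0;
        double ssum = 0;
        for (int k = 0; k < n; ++k) {
          double s = (k + 0.5) / n * 2.0 - 1.0;
          ssum += 1.0 - s * s;
        }
        double scale = mean * n / ssum;
        for (int k = 0; k < n; ++k) {
          double s = (k + 0.5) / n * 2.0 - 1.0;
          f.vbc[g.FY(i0 + k, j)] = sgn * scale * (1.0 - s * s);
        }
      } else ++i;
    }
  }
}

// ---------------------------------------------------------------------------
// contact-angle ghost fill: solid cells adjacent to fluid receive a phi value
// extrapolated so the interface meets the wall at angle theta, measured
// through the dispersed (phi = 1) phase. With the interface normal
// n = grad(phi)/|grad phi| (pointing into the dispersed phase) and w the
// wall normal into the fluid, the geometric condition is n . w = -cos(theta),
// i.e. (phi_fluid - phi_ghost)/h = -|grad phi| cos(theta): theta > pi/2
// makes walls look continuous-phase-like (non-wetting dispersed phase).
static void fill_contact_ghosts(const Grid& g, std::vector<double>& phi,
                                double theta) {
  double ct = std::cos(theta);
  int nx = g.nx, ny = g.ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (g.fluid[g.C(i, j)]) continue;
      double sum = 0; int n = 0;
      double gsum = 0;
      const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
      for (int k = 0; k < 4; ++k) {
        int ii = i + di[k], jj = j + dj[k];
        if (g.fl(ii, jj)) {
          double pf = phi[g.C(ii, jj)];
          sum += pf; ++n;
          // tangential gradient magnitude estimate at the fluid neighbour
          double gx = 0, gy = 0;
          if (di[k] == 0) {           // wall normal is y -> tangent x
            double pl = g.fl(ii - 1, jj) ? phi[g.C(ii - 1, jj)] : pf;
            double pr = g.fl(ii + 1, jj) ? phi[g.C(ii + 1, jj)] : pf;
            gx = (pr - pl) / (2 * g.h);
          } else {
            double pb = g.fl(ii, jj - 1) ? phi[g.C(ii, jj - 1)] : pf;
            double pt = g.fl(ii, jj + 1) ? phi[g.C(ii, jj + 1)] : pf;
            gy = (pt - pb) / (2 * g.h);
          }
          gsum += std::sqrt(gx * gx + gy * gy);
        }
      }
      if (n > 0) {
        double gmag = gsum / n;
        double val = sum / n + g.h * ct * gmag;
        phi[g.C(i, j)] = std::min(1.0, std::max(0.0, val));
      }
    }
}

// ---------------------------------------------------------------------------
// generic preconditioned CG, matrix-free.
// A is applied through `Ax`; `prec(r, z)` applies the preconditioner;
// `freeNode` marks unknowns. Returns iterations used.
struct CGWork {
  std::vector<double> r, z, pvec, Ap;
};

template <class MatVec, class Precond>
static int cg_solve_pc(int n, const std::vector<uint8_t>& freeNode,
                       MatVec Ax, Precond prec,
                       const std::vector<double>& b, std::vector<double>& x,
                       double tol_rel, int maxit, CGWork& w) {
  w.r.assign(n, 0.0); w.z.assign(n, 0.0);
  w.pvec.assign(n, 0.0); w.Ap.assign(n, 0.0);
  Ax(x, w.Ap);
  double bnorm2 = 0;
  for (int k = 0; k < n; ++k) if (freeNode[k]) {
    w.r[k] = b[k] - w.Ap[k];
    bnorm2 += b[k] * b[k];
  }
  if (bnorm2 == 0) {
    for (int k = 0; k < n; ++k) if (freeNode[k]) x[k] = 0.0;
    return 0;
  }
  double tol2 = tol_rel * tol_rel * bnorm2;
  prec(w.r, w.z);
  double rz = 0;
  for (int k = 0; k < n; ++k) if (freeNode[k]) {
    w.pvec[k] = w.z[k];
    rz += w.r[k] * w.z[k];
  }
  int it = 0;
  double rn2 = 0;
  for (int k = 0; k < n; ++k) if (freeNode[k]) rn2 += w.r[k] * w.r[k];
  while (rn2 > tol2 && it < maxit) {
    Ax(w.pvec, w.Ap);
    double pAp = 0;
    for (int k = 0; k < n; ++k) if (freeNode[k]) pAp += w.pvec[k] * w.Ap[k];
    if (pAp <= 0) break;
    double alpha = rz / pAp;
    rn2 = 0;
    for (int k = 0; k < n; ++k) if (freeNode[k]) {
      x[k] += alpha * w.pvec[k];
      w.r[k] -= alpha * w.Ap[k];
      rn2 += w.r[k] * w.r[k];
    }
    if (rn2 <= tol2) { ++it; break; }
    prec(w.r, w.z);
    double rznew = 0;
    for (int k = 0; k < n; ++k) if (freeNode[k]) rznew += w.r[k] * w.z[k];
    double beta = rznew / rz;
    rz = rznew;
    for (int k = 0; k < n; ++k) if (freeNode[k])
      w.pvec[k] = w.z[k] + beta * w.pvec[k];
    ++it;
  }
  return it;
}

template <class MatVec>
static int cg_solve(int n, const std::vector<uint8_t>& freeNode,
                    const std::vector<double>& diag, MatVec Ax,
                    const std::vector<double>& b, std::vector<double>& x,
                    double tol_rel, int maxit, CGWork& w) {
  w.r.assign(n, 0.0); w.z.assign(n, 0.0);
  w.pvec.assign(n, 0.0); w.Ap.assign(n, 0.0);
  Ax(x, w.Ap);
  double bnorm2 = 0;
  for (int k = 0; k < n; ++k) if (freeNode[k]) {
    w.r[k] = b[k] - w.Ap[k];
    bnorm2 += b[k] * b[k];
  }
  if (bnorm2 == 0) {
    for (int k = 0; k < n; ++k) if (freeNode[k]) x[k] = 0.0;
    return 0;
  }
  double tol2 = tol_rel * tol_rel * bnorm2;
  double rz = 0;
  for (int k = 0; k < n; ++k) if (freeNode[k]) {
    w.z[k] = w.r[k] / diag[k];
    w.pvec[k] = w.z[k];
    rz += w.r[k] * w.z[k];
  }
  int it = 0;
  double rn2 = 0;
  for (int k = 0; k < n; ++k) if (freeNode[k]) rn2 += w.r[k] * w.r[k];
  while (rn2 > tol2 && it < maxit) {
    Ax(w.pvec, w.Ap);
    double pAp = 0;
    for (int k = 0; k < n; ++k) if (freeNode[k]) pAp += w.pvec[k] * w.Ap[k];
    if (pAp <= 0) break;
    double alpha = rz / pAp;
    rn2 = 0;
    for (int k = 0; k < n; ++k) if (freeNode[k]) {
      x[k] += alpha * w.pvec[k];
      w.r[k] -= alpha * w.Ap[k];
      rn2 += w.r[k] * w.r[k];
    }
    if (rn2 <= tol2) { ++it; break; }
    double rznew = 0;
    for (int k = 0; k < n; ++k) if (freeNode[k]) {
      w.z[k] = w.r[k] / diag[k];
      rznew += w.r[k] * w.z[k];
    }
    double beta = rznew / rz;
    rz = rznew;
    for (int k = 0; k < n; ++k) if (freeNode[k])
      w.pvec[k] = w.z[k] + beta * w.pvec[k];
    ++it;
  }
  return it;
}

// ---------------------------------------------------------------------------
// geometric multigrid preconditioner for the pressure Poisson equation.
// Built once per run from the fluid mask with a constant reference mobility
// (the density ratio is close to 1, so the constant-coefficient hierarchy
// is spectrally close to the variable-coefficient operator).
// Coarsening: 2x2 cell agglomeration; coarse operators by Galerkin sums
// over the fine 5-point stencil (piecewise-constant prolongation).
// intermediate full-array representation used while building the hierarchy
struct MGBuild {
  int nx, ny, n;
  std::vector<uint8_t> fluid;
  std::vector<double> diag, cE, cN;   // couplings to east/north neighbour
  std::vector<int> parent;            // cell -> coarse cell index (full grid)
  inline int C(int i, int j) const { return i + j * nx; }
};

// compressed per-level storage over fluid cells only
struct MGLevel {
  int ncell = 0;
  std::vector<int> nb;                // 4*ncell neighbour list indices (-1)
  std::vector<double> cf;             // 4*ncell couplings
  std::vector<double> diag;
  std::vector<uint8_t> red;           // checkerboard colour
  std::vector<int> parent;            // list index on the coarser level
  std::vector<double> x, b, r;
  std::vector<int> cell;              // list -> full-grid index (level 0 use)
};

struct MGPrecond {
  std::vector<MGLevel> lev;
  int nu_coarse = 100;
  bool has_outlet = true;             // all-Neumann problems need deflation
  std::vector<int> map0;              // full grid -> level-0 list index

  inline static double rowsum(const MGLevel& L, int k) {
    double s = L.diag[k] * L.x[k];
    for (int q = 0; q < 4; ++q) {
      int nb = L.nb[4 * k + q];
      if (nb >= 0) s -= L.cf[4 * k + q] * L.x[nb];
    }
    return s;
  }
  // red-black Gauss-Seidel; forward = red then black
  static void rbgs(MGLevel& L, bool forward) {
    for (int pass = 0; pass < 2; ++pass) {
      uint8_t want = forward ? (pass == 0) : (pass == 1);
      for (int k = 0; k < L.ncell; ++k) {
        if (L.red[k] != want) continue;
        double s = L.b[k];
        for (int q = 0; q < 4; ++q) {
          int nb = L.nb[4 * k + q];
          if (nb >= 0) s += L.cf[4 * k + q] * L.x[nb];
        }
        L.x[k] = s / L.diag[k];
      }
    }
  }
  void vcycle(size_t l) {
    MGLevel& L = lev[l];
    if (l + 1 == lev.size()) {
      for (int s = 0; s < nu_coarse; ++s) rbgs(L, s % 2 == 0);
      return;
    }
    rbgs(L, true);                       // pre-smooth (red-black)
    MGLevel& C = lev[l + 1];
    std::fill(C.b.begin(), C.b.end(), 0.0);
    std::fill(C.x.begin(), C.x.end(), 0.0);
    for (int k = 0; k < L.ncell; ++k)
      C.b[L.parent[k]] += L.b[k] - rowsum(L, k);
    vcycle(l + 1);
    for (int k = 0; k < L.ncell; ++k) L.x[k] += C.x[L.parent[k]];
    rbgs(L, false);                      // post-smooth (black-red: symmetric)
  }
  // z = M^{-1} r (one symmetric V-cycle from zero initial guess);
  // r and z live on the full grid
  void apply(const std::vector<double>& r, std::vector<double>& z) {
    MGLevel& L = lev[0];
    for (int k = 0; k < L.ncell; ++k) L.b[k] = r[L.cell[k]];
    if (!has_outlet) {                // remove the constant null-space mode
      double m = 0;
      for (int k = 0; k < L.ncell; ++k) m += L.b[k];
      m /= L.ncell;
      for (int k = 0; k < L.ncell; ++k) L.b[k] -= m;
    }
    std::fill(L.x.begin(), L.x.end(), 0.0);
    vcycle(0);
    if (!has_outlet) {
      double m = 0;
      for (int k = 0; k < L.ncell; ++k) m += L.x[k];
      m /= L.ncell;
      for (int k = 0; k < L.ncell; ++k) L.x[k] -= m;
    }
    for (int k = 0; k < L.ncell; ++k) z[L.cell[k]] = L.x[k];
  }
};

struct Solver {
  Grid g;
  FaceInfo fc;
  double rho_c, rho_d, mu_c, mu_d, sigma, theta, gamma_ls, eps_ls;
  bool gamma_auto = false;   // gamma = current max |velocity| (recomputed)
  double u_c, u_d;
  double p_tol;
  std::vector<double> u, v, p, phi;
  std::vector<double> rho, mu;                  // cell
  std::vector<double> munode;                   // (nx+1) x (ny+1) nodes
  std::vector<double> rhoFx, rhoFy, betaFx, betaFy;  // face averages
  std::vector<double> ustar, vstar, Fx, Fy, kappa;
  std::vector<double> rhs, diagP, dp;
  std::vector<uint8_t> pfree;
  MGPrecond mg;
  std::vector<double> bu, bv, diagU, diagV;
  std::vector<uint8_t> ufree, vfree;
  std::vector<double> phinew;
  CGWork wk;
  double t = 0.0;
  int last_cg_iters = 0;

  void init_from(const Grid& gg) {
    g = gg;
    int nc = g.nx * g.ny, nu = (g.nx + 1) * g.ny, nv = g.nx * (g.ny + 1);
    u.assign(nu, 0.0); v.assign(nv, 0.0);
    p.assign(nc, 0.0); phi.assign(nc, 0.0);
    rho.assign(nc, 0.0); mu.assign(nc, 0.0);
    ustar.assign(nu, 0.0); vstar.assign(nv, 0.0);
    Fx.assign(nu, 0.0); Fy.assign(nv, 0.0);
    kappa.assign(nc, 0.0);
    rhs.assign(nc, 0.0); diagP.assign(nc, 1.0); pfree.assign(nc, 0);
    bu.assign(nu, 0.0); bv.assign(nv, 0.0);
    diagU.assign(nu, 1.0); diagV.assign(nv, 1.0);
    ufree.assign(nu, 0); vfree.assign(nv, 0);
    phinew.assign(nc, 0.0);
    munode.assign((g.nx + 1) * (g.ny + 1), mu_c);
    rhoFx.assign(nu, rho_c); betaFx.assign(nu, 1.0 / rho_c);
    rhoFy.assign(nv, rho_c); betaFy.assign(nv, 1.0 / rho_c);
    for (int k = 0; k < nc; ++k) pfree[k] = g.fluid[k];
    for (int k = 0; k < nu; ++k) ufree[k] = (fc.ukind[k] == 1);
    for (int k = 0; k < nv; ++k) vfree[k] = (fc.vkind[k] == 1);
    dp.assign(nc, 0.0);
    build_mg();
  }

  void build_mg() {
    double beta0 = 2.0 / (rho_c + rho_d);
    double h2 = g.h * g.h;
    std::vector<MGBuild> blds;
    MGBuild L0;
    L0.nx = g.nx; L0.ny = g.ny; L0.n = g.nx * g.ny;
    L0.fluid = g.fluid;
    L0.diag.assign(L0.n, 0.0);
    L0.cE.assign(L0.n, 0.0);
    L0.cN.assign(L0.n, 0.0);
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        int c = L0.C(i, j);
        if (!g.fluid[c]) continue;
        if (fc.ukind[g.FX(i + 1, j)] == 1) L0.cE[c] = beta0 / h2;
        if (fc.vkind[g.FY(i, j + 1)] == 1) L0.cN[c] = beta0 / h2;
      }
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        int c = L0.C(i, j);
        if (!g.fluid[c]) continue;
        double d = L0.cE[c] + L0.cN[c];
        if (i > 0) d += L0.cE[c - 1];
        if (j > 0) d += L0.cN[c - L0.nx];
        if (fc.ukind[g.FX(i, j)] == 3) d += 2.0 * beta0 / h2;
        if (fc.ukind[g.FX(i + 1, j)] == 3) d += 2.0 * beta0 / h2;
        if (fc.vkind[g.FY(i, j)] == 3) d += 2.0 * beta0 / h2;
        if (fc.vkind[g.FY(i, j + 1)] == 3) d += 2.0 * beta0 / h2;
        L0.diag[c] = d;
      }
    blds.push_back(std::move(L0));
    while (blds.size() < 15) {
      MGBuild& F = blds.back();
      int nfl = 0;
      for (int c = 0; c < F.n; ++c) if (F.fluid[c]) ++nfl;
      if (nfl <= 150 || F.nx < 4 || F.ny < 4) break;
      MGBuild C;
      C.nx = (F.nx + 1) / 2; C.ny = (F.ny + 1) / 2;
      C.n = C.nx * C.ny;
      C.fluid.assign(C.n, 0);
      C.diag.assign(C.n, 0.0);
      C.cE.assign(C.n, 0.0);
      C.cN.assign(C.n, 0.0);
      F.parent.assign(F.n, -1);
      for (int j = 0; j < F.ny; ++j)
        for (int i = 0; i < F.nx; ++i) {
          int c = F.C(i, j);
          int pc = (i / 2) + (j / 2) * C.nx;
          F.parent[c] = pc;
          if (F.fluid[c]) C.fluid[pc] = 1;
        }
      // Galerkin sums over the fine stencil (piecewise-constant prolongation)
      for (int j = 0; j < F.ny; ++j)
        for (int i = 0; i < F.nx; ++i) {
          int c = F.C(i, j);
          if (!F.fluid[c]) continue;
          int pc = F.parent[c];
          C.diag[pc] += F.diag[c];
          if (F.cE[c] != 0) {
            int pe = F.parent[c + 1];
            if (pe == pc) C.diag[pc] -= 2.0 * F.cE[c];
            else C.cE[pc] += F.cE[c];
          }
          if (F.cN[c] != 0) {
            int pn = F.parent[c + F.nx];
            if (pn == pc) C.diag[pc] -= 2.0 * F.cN[c];
            else C.cN[pc] += F.cN[c];
          }
        }
      // piecewise-constant Galerkin coarsening makes the coarse operator
      // about twice too stiff for the Laplacian; rescale so the coarse
      // correction has the right magnitude (standard cell-centred MG fix)
      for (int c = 0; c < C.n; ++c) {
        C.diag[c] *= 0.5; C.cE[c] *= 0.5; C.cN[c] *= 0.5;
      }
      blds.push_back(std::move(C));
    }
    // compress each level to fluid-cell lists
    mg.lev.clear();
    mg.lev.resize(blds.size());
    std::vector<std::vector<int>> maps(blds.size());
    for (size_t l = 0; l < blds.size(); ++l) {
      const MGBuild& B = blds[l];
      MGLevel& L = mg.lev[l];
      maps[l].assign(B.n, -1);
      for (int j = 0; j < B.ny; ++j)
        for (int i = 0; i < B.nx; ++i) {
          int c = B.C(i, j);
          if (!B.fluid[c]) continue;
          maps[l][c] = L.ncell++;
          L.cell.push_back(c);
          L.red.push_back((uint8_t)((i + j) % 2));
          L.diag.push_back(B.diag[c]);
        }
      L.nb.assign(4 * L.ncell, -1);
      L.cf.assign(4 * L.ncell, 0.0);
      for (int k = 0; k < L.ncell; ++k) {
        int c = L.cell[k];
        int i = c % B.nx, j = c / B.nx;
        if (i + 1 < B.nx && B.cE[c] != 0) {
          L.nb[4 * k] = maps[l][c + 1]; L.cf[4 * k] = B.cE[c];
        }
        if (i > 0 && B.cE[c - 1] != 0) {
          L.nb[4 * k + 1] = maps[l][c - 1]; L.cf[4 * k + 1] = B.cE[c - 1];
        }
        if (j + 1 < B.ny && B.cN[c] != 0) {
          L.nb[4 * k + 2] = maps[l][c + B.nx]; L.cf[4 * k + 2] = B.cN[c];
        }
        if (j > 0 && B.cN[c - B.nx] != 0) {
          L.nb[4 * k + 3] = maps[l][c - B.nx]; L.cf[4 * k + 3] = B.cN[c - B.nx];
        }
      }
      L.x.assign(L.ncell, 0.0);
      L.b.assign(L.ncell, 0.0);
      L.r.assign(L.ncell, 0.0);
    }
    for (size_t l = 0; l + 1 < blds.size(); ++l) {
      MGLevel& L = mg.lev[l];
      L.parent.assign(L.ncell, -1);
      for (int k = 0; k < L.ncell; ++k)
        L.parent[k] = maps[l + 1][blds[l].parent[L.cell[k]]];
    }
    mg.map0 = maps[0];
    mg.has_outlet = false;
    for (size_t k = 0; k < g.xtag.size(); ++k)
      if (g.xtag[k] == TAG_OUT) mg.has_outlet = true;
    for (size_t k = 0; k < g.ytag.size(); ++k)
      if (g.ytag[k] == TAG_OUT) mg.has_outlet = true;
  }

  inline double uval(int i, int j) const {
    // value of u at face (i,j) honouring BCs; inactive -> 0
    int id = g.FX(i, j);
    switch (fc.ukind[id]) {
      case 1: case 3: return u[id];
      case 2: return fc.ubc[id];
      default: return 0.0;
    }
  }
  inline double vval(int i, int j) const {
    int id = g.FY(i, j);
    switch (fc.vkind[id]) {
      case 1: case 3: return v[id];
      case 2: return fc.vbc[id];
      default: return 0.0;
    }
  }
  inline double phiv(int i, int j) const {
    // phi with ghost values in solid cells (contact angle), clamped outside
    if (i < 0) i = 0; if (i >= g.nx) i = g.nx - 1;
    if (j < 0) j = 0; if (j >= g.ny) j = g.ny - 1;
    return phi[g.C(i, j)];
  }

  void update_properties() {
    int nc = g.nx * g.ny;
    for (int k = 0; k < nc; ++k) {
      double f = g.fluid[k] ? phi[k] : 0.0;
      rho[k] = rho_c + (rho_d - rho_c) * f;
      mu[k] = mu_c + (mu_d - mu_c) * f;
    }
    int nx = g.nx, ny = g.ny;
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i <= nx; ++i)
        munode[i + j * (nx + 1)] = mu_node(i, j);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        double r = rho_faceX(i, j);
        rhoFx[g.FX(i, j)] = r;
        betaFx[g.FX(i, j)] = 1.0 / r;
      }
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double r = rho_faceY(i, j);
        rhoFy[g.FY(i, j)] = r;
        betaFy[g.FY(i, j)] = 1.0 / r;
      }
  }
  inline double mn(int i, int j) const { return munode[i + j * (g.nx + 1)]; }

  // cell curvature kappa = -div( grad phi / |grad phi| ) via face normals
  void compute_curvature() {
    int nx = g.nx, ny = g.ny;
    double h = g.h;
    std::fill(kappa.begin(), kappa.end(), 0.0);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!g.fluid[g.C(i, j)]) continue;
        double pc = phi[g.C(i, j)];
        if (pc < 1e-4 || pc > 1.0 - 1e-4) {
          // only near the interface (neighbours may still straddle)
          bool near = false;
          for (int di = -1; di <= 1 && !near; ++di)
            for (int dj = -1; dj <= 1 && !near; ++dj) {
              double q = phiv(i + di, j + dj);
              if (q > 1e-4 && q < 1.0 - 1e-4) near = true;
            }
          if (!near) continue;
        }
        // face-normal components at the four faces of the cell
        double nxE, nyE, nxW, nyW, nxN, nyN, nxS, nyS;
        auto facex = [&](int ii, int jj, double& ox, double& oy) {
          // x-face between (ii-1,jj) and (ii,jj)
          double gx = (phiv(ii, jj) - phiv(ii - 1, jj)) / h;
          double gy = (phiv(ii - 1, jj + 1) + phiv(ii, jj + 1) -
                       phiv(ii - 1, jj - 1) - phiv(ii, jj - 1)) / (4 * h);
          double m = std::sqrt(gx * gx + gy * gy);
          if (m < 1e-12) { ox = 0; oy = 0; } else { ox = gx / m; oy = gy / m; }
        };
        auto facey = [&](int ii, int jj, double& ox, double& oy) {
          double gy = (phiv(ii, jj) - phiv(ii, jj - 1)) / h;
          double gx = (phiv(ii + 1, jj - 1) + phiv(ii + 1, jj) -
                       phiv(ii - 1, jj - 1) - phiv(ii - 1, jj)) / (4 * h);
          double m = std::sqrt(gx * gx + gy * gy);
          if (m < 1e-12) { ox = 0; oy = 0; } else { ox = gx / m; oy = gy / m; }
        };
        facex(i + 1, j, nxE, nyE);
        facex(i, j, nxW, nyW);
        facey(i, j + 1, nxN, nyN);
        facey(i, j, nxS, nyS);
        kappa[g.C(i, j)] = -((nxE - nxW) + (nyN - nyS)) / h;
      }
  }

  // balanced-force CSF: F = sigma * kappa * grad(phi) evaluated at faces
  void compute_surface_tension() {
    int nx = g.nx, ny = g.ny;
    double h = g.h;
    std::fill(Fx.begin(), Fx.end(), 0.0);
    std::fill(Fy.begin(), Fy.end(), 0.0);
    if (sigma <= 0) return;
    fill_contact_ghosts(g, phi, theta);   // ghosts feed the gradients below
    compute_curvature();
    for (int j = 0; j < ny; ++j)
      for (int i = 1; i < nx; ++i) {
        int id = g.FX(i, j);
        if (fc.ukind[id] != 1) continue;
        double dphi = phi[g.C(i, j)] - phi[g.C(i - 1, j)];
        if (dphi == 0.0) continue;
        double k2 = 0.5 * (kappa[g.C(i, j)] + kappa[g.C(i - 1, j)]);
        Fx[id] = sigma * k2 * dphi / h;
      }
    for (int j = 1; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = g.FY(i, j);
        if (fc.vkind[id] != 1) continue;
        double dphi = phi[g.C(i, j)] - phi[g.C(i, j - 1)];
        if (dphi == 0.0) continue;
        double k2 = 0.5 * (kappa[g.C(i, j)] + kappa[g.C(i, j - 1)]);
        Fy[id] = sigma * k2 * dphi / h;
      }
  }

  inline double mu_node(int i, int j) const {
    // viscosity at grid node (i,j) = corner shared by cells
    // (i-1,j-1),(i,j-1),(i-1,j),(i,j); average over fluid cells
    double s = 0; int n = 0;
    const int ci[4] = {i - 1, i, i - 1, i}, cj[4] = {j - 1, j - 1, j, j};
    for (int k = 0; k < 4; ++k)
      if (g.fl(ci[k], cj[k])) { s += mu[g.C(ci[k], cj[k])]; ++n; }
    return n ? s / n : mu_c;
  }
  inline double rho_faceX(int i, int j) const {
    double s = 0; int n = 0;
    if (g.fl(i - 1, j)) { s += rho[g.C(i - 1, j)]; ++n; }
    if (g.fl(i, j)) { s += rho[g.C(i, j)]; ++n; }
    return n ? s / n : rho_c;
  }
  inline double rho_faceY(int i, int j) const {
    double s = 0; int n = 0;
    if (g.fl(i, j - 1)) { s += rho[g.C(i, j - 1)]; ++n; }
    if (g.fl(i, j)) { s += rho[g.C(i, j)]; ++n; }
    return n ? s / n : rho_c;
  }

  // explicit upwind advection of u and v (non-conservative form)
  void advect_velocity(double dt) {
    int nx = g.nx, ny = g.ny;
    double h = g.h;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int id = g.FX(i, j);
        if (fc.ukind[id] != 1) {
          ustar[id] = (fc.ukind[id] == 2) ? fc.ubc[id] : u[id];
          continue;
        }
        double uc = u[id];
        // u neighbours with wall reflection for tangential ghosts
        double uW = uval(i - 1, j), uE = uval(i + 1, j);
        double uS, uN;
        {
          int idS = (j > 0) ? g.FX(i, j - 1) : -1;
          if (j > 0 && fc.ukind[idS] != 0)
            uS = (fc.ukind[idS] == 2) ? fc.ubc[idS] : u[idS];
          else uS = -uc;      // no-slip wall below
          int idN = (j < ny - 1) ? g.FX(i, j + 1) : -1;
          if (j < ny - 1 && fc.ukind[idN] != 0)
            uN = (fc.ukind[idN] == 2) ? fc.ubc[idN] : u[idN];
          else uN = -uc;
        }
        double vbar = 0.25 * (vval(i - 1, j) + vval(i, j) +
                              vval(i - 1, j + 1) + vval(i, j + 1));
        double dudx = (uc > 0) ? (uc - uW) / h : (uE - uc) / h;
        double dudy = (vbar > 0) ? (uc - uS) / h : (uN - uc) / h;
        ustar[id] = uc - dt * (uc * dudx + vbar * dudy);
      }
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = g.FY(i, j);
        if (fc.vkind[id] != 1) {
          vstar[id] = (fc.vkind[id] == 2) ? fc.vbc[id] : v[id];
          continue;
        }
        double vc = v[id];
        double vS = vval(i, j - 1), vN = vval(i, j + 1);
        double vW, vE;
        {
          int idW = (i > 0) ? g.FY(i - 1, j) : -1;
          if (i > 0 && fc.vkind[idW] != 0)
            vW = (fc.vkind[idW] == 2) ? fc.vbc[idW] : v[idW];
          else vW = -vc;
          int idE = (i < nx - 1) ? g.FY(i + 1, j) : -1;
          if (i < nx - 1 && fc.vkind[idE] != 0)
            vE = (fc.vkind[idE] == 2) ? fc.vbc[idE] : v[idE];
          else vE = -vc;
        }
        double ubar = 0.25 * (uval(i, j - 1) + uval(i + 1, j - 1) +
                              uval(i, j) + uval(i + 1, j));
        double dvdy = (vc > 0) ? (vc - vS) / h : (vN - vc) / h;
        double dvdx = (ubar > 0) ? (vc - vW) / h : (vE - vc) / h;
        vstar[id] = vc - dt * (ubar * dvdx + vc * dvdy);
      }
  }

  // explicit transpose-stress remainder for the x momentum:
  //   d/dx(mu du/dx) + d/dy(mu dv/dx)
  double transX(int i, int j) const {
    double h = g.h;
    double uxR = (uval(i + 1, j) - uval(i, j)) / h;       // at cell (i,j)
    double uxL = (uval(i, j) - uval(i - 1, j)) / h;       // at cell (i-1,j)
    double muR = g.fl(i, j) ? mu[g.C(i, j)] : mu_c;
    double muL = g.fl(i - 1, j) ? mu[g.C(i - 1, j)] : mu_c;
    double t1 = (muR * uxR - muL * uxL) / h;
    double vxN = (vval(i, j + 1) - vval(i - 1, j + 1)) / h;  // node (i,j+1)
    double vxS = (vval(i, j) - vval(i - 1, j)) / h;          // node (i,j)
    double t2 = (mn(i, j + 1) * vxN - mn(i, j) * vxS) / h;
    return t1 + t2;
  }
  double transY(int i, int j) const {
    double h = g.h;
    double vyT = (vval(i, j + 1) - vval(i, j)) / h;
    double vyB = (vval(i, j) - vval(i, j - 1)) / h;
    double muT = g.fl(i, j) ? mu[g.C(i, j)] : mu_c;
    double muB = g.fl(i, j - 1) ? mu[g.C(i, j - 1)] : mu_c;
    double t1 = (muT * vyT - muB * vyB) / h;
    double uyE = (uval(i + 1, j) - uval(i + 1, j - 1)) / h;  // node (i+1,j)
    double uyW = (uval(i, j) - uval(i, j - 1)) / h;          // node (i,j)
    double t2 = (mn(i + 1, j) * uyE - mn(i, j) * uyW) / h;
    return t1 + t2;
  }

  // implicit viscous solve for ustar/vstar (backward Euler on div(mu grad))
  void viscous_solve(double dt) {
    int nx = g.nx, ny = g.ny;
    double h = g.h, h2 = h * h;
    // ---- u component -------------------------------------------------
    int nu = (nx + 1) * ny;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int id = g.FX(i, j);
        if (fc.ukind[id] != 1) continue;
        double rf = rhoFx[g.FX(i, j)];
        double aP = rf / dt;
        double muE = mu[g.C(i, j)], muW = mu[g.C(i - 1, j)];
        double muN = mn(i, j + 1), muS = mn(i, j);
        double b = rf / dt * ustar[id] + Fx[id] + transX(i, j) -
                   (p[g.C(i, j)] - p[g.C(i - 1, j)]) / h;   // incremental
        // east/west neighbours are u(i+1,j), u(i-1,j) at distance h
        auto addnb = [&](int ii, int jj, double m) {
          int nid = g.FX(ii, jj);
          uint8_t k = (ii >= 0 && ii <= nx && jj >= 0 && jj < ny)
                          ? fc.ukind[nid] : (uint8_t)0;
          if (k == 1) { aP += m / h2; }
          else if (k == 2) { aP += m / h2; b += m / h2 * fc.ubc[nid]; }
          else if (k == 3) { aP += m / h2; b += m / h2 * u[nid]; }
          else {
            // tangential wall ghost u = -u  ->  2m/h2 on the diagonal,
            // only for the north/south direction; for e/w an inactive
            // neighbour means a solid corner: treat as wall too
            aP += 2.0 * m / h2;
          }
        };
        addnb(i + 1, j, muE);
        addnb(i - 1, j, muW);
        addnb(i, j + 1, muN);
        addnb(i, j - 1, muS);
        diagU[id] = aP;
        bu[id] = b;
      }
    auto AxU = [&](const std::vector<double>& x, std::vector<double>& y) {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i <= nx; ++i) {
          int id = g.FX(i, j);
          if (fc.ukind[id] != 1) continue;
          double muE = mu[g.C(i, j)], muW = mu[g.C(i - 1, j)];
          double muN = mn(i, j + 1), muS = mn(i, j);
          double s = diagU[id] * x[id];
          if (i + 1 <= nx && fc.ukind[g.FX(i + 1, j)] == 1)
            s -= muE / h2 * x[g.FX(i + 1, j)];
          if (i - 1 >= 0 && fc.ukind[g.FX(i - 1, j)] == 1)
            s -= muW / h2 * x[g.FX(i - 1, j)];
          if (j + 1 < ny && fc.ukind[g.FX(i, j + 1)] == 1)
            s -= muN / h2 * x[g.FX(i, j + 1)];
          if (j - 1 >= 0 && fc.ukind[g.FX(i, j - 1)] == 1)
            s -= muS / h2 * x[g.FX(i, j - 1)];
          y[id] = s;
        }
    };
    cg_solve(nu, ufree, diagU, AxU, bu, ustar, 1e-9, 500, wk);
    // ---- v component -------------------------------------------------
    int nv = nx * (ny + 1);
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = g.FY(i, j);
        if (fc.vkind[id] != 1) continue;
        double rf = rhoFy[g.FY(i, j)];
        double aP = rf / dt;
        double muN = mu[g.C(i, j)], muS = mu[g.C(i, j - 1)];
        double muE = mn(i + 1, j), muW = mn(i, j);
        double b = rf / dt * vstar[id] + Fy[id] + transY(i, j) -
                   (p[g.C(i, j)] - p[g.C(i, j - 1)]) / h;
        auto addnb = [&](int ii, int jj, double m) {
          int nid = g.FY(ii, jj);
          uint8_t k = (ii >= 0 && ii < nx && jj >= 0 && jj <= ny)
                          ? fc.vkind[nid] : (uint8_t)0;
          if (k == 1) { aP += m / h2; }
          else if (k == 2) { aP += m / h2; b += m / h2 * fc.vbc[nid]; }
          else if (k == 3) { aP += m / h2; b += m / h2 * v[nid]; }
          else { aP += 2.0 * m / h2; }
        };
        addnb(i, j + 1, muN);
        addnb(i, j - 1, muS);
        addnb(i + 1, j, muE);
        addnb(i - 1, j, muW);
        diagV[id] = aP;
        bv[id] = b;
      }
    auto AxV = [&](const std::vector<double>& x, std::vector<double>& y) {
      for (int j = 0; j <= ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int id = g.FY(i, j);
          if (fc.vkind[id] != 1) continue;
          double muN = mu[g.C(i, j)], muS = mu[g.C(i, j - 1)];
          double muE = mn(i + 1, j), muW = mn(i, j);
          double s = diagV[id] * x[id];
          if (j + 1 <= ny && fc.vkind[g.FY(i, j + 1)] == 1)
            s -= muN / h2 * x[g.FY(i, j + 1)];
          if (j - 1 >= 0 && fc.vkind[g.FY(i, j - 1)] == 1)
            s -= muS / h2 * x[g.FY(i, j - 1)];
          if (i + 1 < nx && fc.vkind[g.FY(i + 1, j)] == 1)
            s -= muE / h2 * x[g.FY(i + 1, j)];
          if (i - 1 >= 0 && fc.vkind[g.FY(i - 1, j)] == 1)
            s -= muW / h2 * x[g.FY(i - 1, j)];
          y[id] = s;
        }
    };
    cg_solve(nv, vfree, diagV, AxV, bv, vstar, 1e-9, 500, wk);
  }

  // pressure projection; returns max divergence after correction
  double project(double dt) {
    int nx = g.nx, ny = g.ny;
    double h = g.h, h2 = h * h;
    // outlet faces: zero normal gradient of the predictor velocity; the
    // pressure-increment correction below (Dirichlet p = 0 at the face)
    // then enforces global mass balance
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int id = g.FX(i, j);
        if (fc.ukind[id] == 3) {
          int ii = g.fl(i - 1, j) ? i - 1 : i + 1;
          int nid = g.FX(ii, j);
          ustar[id] = (fc.ukind[nid] == 1) ? ustar[nid]
                      : (fc.ukind[nid] == 2) ? fc.ubc[nid] : ustar[id];
        }
      }
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = g.FY(i, j);
        if (fc.vkind[id] == 3) {
          int jj = g.fl(i, j - 1) ? j - 1 : j + 1;
          int nid = g.FY(i, jj);
          vstar[id] = (fc.vkind[nid] == 1) ? vstar[nid]
                      : (fc.vkind[nid] == 2) ? fc.vbc[nid] : vstar[id];
        }
      }
    // assemble rhs = -div(ustar)/dt, diag of A = -div(beta grad)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = g.C(i, j);
        if (!g.fluid[c]) { rhs[c] = 0; diagP[c] = 1; continue; }
        double div = (faceU(i + 1, j, ustar) - faceU(i, j, ustar) +
                      faceV(i, j + 1, vstar) - faceV(i, j, vstar)) / h;
        rhs[c] = -div / dt;
        double aP = 0;
        int idE = g.FX(i + 1, j), idW = g.FX(i, j);
        int idN = g.FY(i, j + 1), idS = g.FY(i, j);
        if (fc.ukind[idE] == 1) aP += betaFx[g.FX(i + 1, j)] / h2;
        else if (fc.ukind[idE] == 3) aP += 2.0 * betaFx[g.FX(i + 1, j)] / h2;
        if (fc.ukind[idW] == 1) aP += betaFx[g.FX(i, j)] / h2;
        else if (fc.ukind[idW] == 3) aP += 2.0 * betaFx[g.FX(i, j)] / h2;
        if (fc.vkind[idN] == 1) aP += betaFy[g.FY(i, j + 1)] / h2;
        else if (fc.vkind[idN] == 3) aP += 2.0 * betaFy[g.FY(i, j + 1)] / h2;
        if (fc.vkind[idS] == 1) aP += betaFy[g.FY(i, j)] / h2;
        else if (fc.vkind[idS] == 3) aP += 2.0 * betaFy[g.FY(i, j)] / h2;
        diagP[c] = (aP > 0) ? aP : 1.0;
      }
    auto AxP = [&](const std::vector<double>& x, std::vector<double>& y) {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int c = g.C(i, j);
          if (!g.fluid[c]) continue;
          double s = diagP[c] * x[c];
          if (fc.ukind[g.FX(i + 1, j)] == 1)
            s -= x[g.C(i + 1, j)] * betaFx[g.FX(i + 1, j)] / h2;
          if (fc.ukind[g.FX(i, j)] == 1)
            s -= x[g.C(i - 1, j)] * betaFx[g.FX(i, j)] / h2;
          if (fc.vkind[g.FY(i, j + 1)] == 1)
            s -= x[g.C(i, j + 1)] * betaFy[g.FY(i, j + 1)] / h2;
          if (fc.vkind[g.FY(i, j)] == 1)
            s -= x[g.C(i, j - 1)] * betaFy[g.FY(i, j)] / h2;
          y[c] = s;
        }
    };
    if (!mg.has_outlet) {
      // all-Neumann problem: project out the incompatible (constant) mode
      double m = 0; int nfl = 0;
      for (int k = 0; k < nx * ny; ++k)
        if (g.fluid[k]) { m += rhs[k]; ++nfl; }
      m /= nfl;
      for (int k = 0; k < nx * ny; ++k) if (g.fluid[k]) rhs[k] -= m;
      m = 0;
      for (int k = 0; k < nx * ny; ++k) if (g.fluid[k]) m += dp[k];
      m /= nfl;
      for (int k = 0; k < nx * ny; ++k) if (g.fluid[k]) dp[k] -= m;
    }
    last_cg_iters = cg_solve_pc(
        (int)p.size(), pfree, AxP,
        [&](const std::vector<double>& r, std::vector<double>& z) {
          mg.apply(r, z);
        },
        rhs, dp, p_tol, 2000, wk);
    for (int k = 0; k < nx * ny; ++k)
      if (g.fluid[k]) p[k] += dp[k];
    // correct velocities with the pressure increment
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int id = g.FX(i, j);
        if (fc.ukind[id] == 1) {
          double beta = betaFx[g.FX(i, j)];
          u[id] = ustar[id] - dt * beta *
                  (dp[g.C(i, j)] - dp[g.C(i - 1, j)]) / h;
        } else if (fc.ukind[id] == 3) {
          // outlet: Dirichlet p = 0 at the face (half-cell gradient);
          // matches the 2*beta/h^2 diagonal term in the Poisson stencil
          double beta = betaFx[g.FX(i, j)];
          double pin = g.fl(i - 1, j) ? dp[g.C(i - 1, j)] : dp[g.C(i, j)];
          double sgn = g.fl(i - 1, j) ? 1.0 : -1.0;   // +x outward if fluid left
          u[id] = ustar[id] + sgn * 2.0 * dt * beta * pin / h;
        } else u[id] = (fc.ukind[id] == 2) ? fc.ubc[id] : 0.0;
      }
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = g.FY(i, j);
        if (fc.vkind[id] == 1) {
          double beta = betaFy[g.FY(i, j)];
          v[id] = vstar[id] - dt * beta *
                  (dp[g.C(i, j)] - dp[g.C(i, j - 1)]) / h;
        } else if (fc.vkind[id] == 3) {
          double beta = betaFy[g.FY(i, j)];
          double pin = g.fl(i, j - 1) ? dp[g.C(i, j - 1)] : dp[g.C(i, j)];
          double sgn = g.fl(i, j - 1) ? 1.0 : -1.0;
          v[id] = vstar[id] + sgn * 2.0 * dt * beta * pin / h;
        } else v[id] = (fc.vkind[id] == 2) ? fc.vbc[id] : 0.0;
      }
    // max divergence
    double dmax = 0;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!g.fluid[g.C(i, j)]) continue;
        double div = (faceU(i + 1, j, u) - faceU(i, j, u) +
                      faceV(i, j + 1, v) - faceV(i, j, v)) / h;
        if (std::fabs(div) > dmax) dmax = std::fabs(div);
      }
    return dmax;
  }

  inline double faceU(int i, int j, const std::vector<double>& arr) const {
    int id = g.FX(i, j);
    switch (fc.ukind[id]) {
      case 1: case 3: return arr[id];
      case 2: return fc.ubc[id];
      default: return 0.0;
    }
  }
  inline double faceV(int i, int j, const std::vector<double>& arr) const {
    int id = g.FY(i, j);
    switch (fc.vkind[id]) {
      case 1: case 3: return arr[id];
      case 2: return fc.vbc[id];
      default: return 0.0;
    }
  }

  // conservative level-set step: advection + gamma * div(eps grad phi -
  // phi(1-phi) nhat); flux form so interior mass moves conservatively
  void levelset_step(double dt, bool periodic_x) {
    int nx = g.nx, ny = g.ny;
    double h = g.h;
    // ghost fill for gradients near walls
    fill_contact_ghosts(g, phi, theta);
    auto PHI = [&](int i, int j) -> double {
      if (periodic_x) { i = (i % nx + nx) % nx; }
      return phiv(i, j);
    };
    // x-face fluxes
    std::vector<double>& fxflux = ustar;  // reuse scratch (momentum done)
    std::vector<double>& fyflux = vstar;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int id = g.FX(i, j);
        double flux = 0.0;
        uint8_t k = fc.ukind[id];
        if (periodic_x && (i == 0 || i == nx)) k = 1;  // test mode: wrap
        if (k == 1) {
          double uf = periodic_x ? u[g.FX(0, j)] : u[id];
          int iL = i - 1, iR = i;
          double phL = PHI(iL, j), phR = PHI(iR, j);
          // van Leer limited (MUSCL) face value: second-order where smooth,
          // monotone at the interface front
          double up;
          if (uf >= 0) {
            double d = phR - phL;
            double r = (std::fabs(d) > 1e-12)
                           ? (phL - PHI(iL - 1, j)) / d : 0.0;
            double psi = (r + std::fabs(r)) / (1.0 + std::fabs(r));
            up = phL + 0.5 * psi * d;
          } else {
            double d = phL - phR;
            double r = (std::fabs(d) > 1e-12)
                           ? (phR - PHI(iR + 1, j)) / d : 0.0;
            double psi = (r + std::fabs(r)) / (1.0 + std::fabs(r));
            up = phR + 0.5 * psi * d;
          }
          flux = uf * up;
          // compressive + diffusive part
          double gx = (phR - phL) / h;
          double gy = (PHI(iL, j + 1) + PHI(iR, j + 1) -
                       PHI(iL, j - 1) - PHI(iR, j - 1)) / (4 * h);
          double m = std::sqrt(gx * gx + gy * gy);
          double phf = 0.5 * (phL + phR);
          double nxf = (m > 1e-9) ? gx / m : 0.0;
          flux -= gamma_ls * (eps_ls * gx - phf * (1.0 - phf) * nxf);
        } else if (k == 2) {
          int t = g.xtag[id];
          double phin_bc = (t == TAG_IND) ? 1.0 : 0.0;
          flux = fc.ubc[id] * phin_bc;
        } else if (k == 3) {
          double uf = u[id];
          bool Lfl = g.fl(i - 1, j);
          double phup;
          if (Lfl) phup = (uf >= 0) ? phi[g.C(i - 1, j)] : 0.0;
          else phup = (uf <= 0) ? phi[g.C(i, j)] : 0.0;
          flux = uf * phup;
        }
        fxflux[id] = flux;
      }
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = g.FY(i, j);
        double flux = 0.0;
        uint8_t k = fc.vkind[id];
        if (k == 1) {
          double vf = v[id];
          double phB = phiv(i, j - 1), phT = phiv(i, j);
          double up;
          if (vf >= 0) {
            double d = phT - phB;
            double r = (std::fabs(d) > 1e-12)
                           ? (phB - phiv(i, j - 2)) / d : 0.0;
            double psi = (r + std::fabs(r)) / (1.0 + std::fabs(r));
            up = phB + 0.5 * psi * d;
          } else {
            double d = phB - phT;
            double r = (std::fabs(d) > 1e-12)
                           ? (phT - phiv(i, j + 1)) / d : 0.0;
            double psi = (r + std::fabs(r)) / (1.0 + std::fabs(r));
            up = phT + 0.5 * psi * d;
          }
          flux = vf * up;
          double gy = (phT - phB) / h;
          double gx = (PHI(i + 1, j - 1) + PHI(i + 1, j) -
                       PHI(i - 1, j - 1) - PHI(i - 1, j)) / (4 * h);
          double m = std::sqrt(gx * gx + gy * gy);
          double phf = 0.5 * (phB + phT);
          double nyf = (m > 1e-9) ? gy / m : 0.0;
          flux -= gamma_ls * (eps_ls * gy - phf * (1.0 - phf) * nyf);
        } else if (k == 2) {
          int t = g.ytag[id];
          double phin_bc = (t == TAG_IND) ? 1.0 : 0.0;
          flux = fc.vbc[id] * phin_bc;
        } else if (k == 3) {
          double vf = v[id];
          bool Bfl = g.fl(i, j - 1);
          double phup;
          if (Bfl) phup = (vf >= 0) ? phi[g.C(i, j - 1)] : 0.0;
          else phup = (vf <= 0) ? phi[g.C(i, j)] : 0.0;
          flux = vf * phup;
        }
        fyflux[id] = flux;
      }
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = g.C(i, j);
        if (!g.fluid[c]) { phinew[c] = phi[c]; continue; }
        double dphi = -(fxflux[g.FX(i + 1, j)] - fxflux[g.FX(i, j)] +
                        fyflux[g.FY(i, j + 1)] - fyflux[g.FY(i, j)]) / h;
        double val = phi[c] + dt * dphi;
        phinew[c] = std::min(1.0, std::max(0.0, val));
      }
    std::swap(phi, phinew);
  }

  double stable_dt(double cfl_adv) {
    double umax = 1e-12;
    for (size_t k = 0; k < u.size(); ++k)
      if (fc.ukind[k] && std::fabs(u[k]) > umax) umax = std::fabs(u[k]);
    for (size_t k = 0; k < v.size(); ++k)
      if (fc.vkind[k] && std::fabs(v[k]) > umax) umax = std::fabs(v[k]);
    for (size_t k = 0; k < fc.ubc.size(); ++k)
      if (std::fabs(fc.ubc[k]) > umax) umax = std::fabs(fc.ubc[k]);
    for (size_t k = 0; k < fc.vbc.size(); ++k)
      if (std::fabs(fc.vbc[k]) > umax) umax = std::fabs(fc.vbc[k]);
    if (gamma_auto) gamma_ls = umax;
    double h = g.h;
    double dt = cfl_adv * h / umax;
    if (sigma > 0) {
      double rbar = 0.5 * (rho_c + rho_d);
      double dt_st = 0.9 * std::sqrt(rbar * h * h * h / (2 * M_PI * sigma));
      if (dt_st < dt) dt = dt_st;
    }
    if (gamma_ls > 0 && eps_ls > 0) {
      double dt_ls = 0.2 * h * h / (gamma_ls * eps_ls);
      if (dt_ls < dt) dt = dt_ls;
    }
    // explicit transpose-stress remainder: coefficient |mu_c - mu_d|
    double dmu = std::fabs(mu_c - mu_d);
    if (dmu > 0) {
      double dt_tr = 0.2 * std::min(rho_c, rho_d) * h * h / dmu;
      if (dt_tr < dt) dt = dt_tr;
    }
    return dt;
  }
};

// ---------------------------------------------------------------------------
// 8-connected labelling of {phi > level} within the fluid mask.
// Returns label image (0 = background), labels start at 1.
static int label_components(const Grid& g, const std::vector<double>& phi,
                            double level, std::vector<int>& lab) {
  int nx = g.nx, ny = g.ny;
  lab.assign(nx * ny, 0);
  int next = 0;
  std::vector<int> stack;
  for (int j0 = 0; j0 < ny; ++j0)
    for (int i0 = 0; i0 < nx; ++i0) {
      int c0 = g.C(i0, j0);
      if (!g.fluid[c0] || phi[c0] <= level || lab[c0]) continue;
      ++next;
      stack.clear();
      stack.push_back(c0);
      lab[c0] = next;
      while (!stack.empty()) {
        int c = stack.back(); stack.pop_back();
        int i = c % nx, j = c / nx;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
            int cc = g.C(ii, jj);
            if (g.fluid[cc] && !lab[cc] && phi[cc] > level) {
              lab[cc] = next;
              stack.push_back(cc);
            }
          }
      }
    }
  return next;
}

static Grid grid_from_R(IntegerVector fluid, IntegerVector xtag,
                        IntegerVector ytag, int nx, int ny, double h_m) {
  Grid g;
  g.nx = nx; g.ny = ny; g.h = h_m;
  g.fluid.assign(fluid.begin(), fluid.end());
  g.xtag.assign(xtag.begin(), xtag.end());
  g.ytag.assign(ytag.begin(), ytag.end());
  return g;
}

// [[Rcpp::export]]
List run_twophase_cpp(IntegerVector fluid, IntegerVector xtag,
                      IntegerVector ytag, int nx, int ny, double h_m,
                      List pars, NumericVector u0, NumericVector v0,
                      NumericVector p0, NumericVector phi0, double t0,
                      double t_end, double dt_fixed, int max_steps,
                      int record_every, IntegerVector probe_cells,
                      bool do_momentum, bool do_levelset, bool periodic_x,
                      double cfl_adv) {
  Solver s;
  Grid g = grid_from_R(fluid, xtag, ytag, nx, ny, h_m);
  s.rho_c = as<double>(pars["rho_c"]);
  s.rho_d = as<double>(pars["rho_d"]);
  s.mu_c = as<double>(pars["mu_c"]);
  s.mu_d = as<double>(pars["mu_d"]);
  s.sigma = as<double>(pars["sigma"]);
  s.theta = as<double>(pars["theta"]);
  s.gamma_ls = as<double>(pars["gamma"]);
  if (s.gamma_ls <= 0) {                 // auto: track max |velocity|
    s.gamma_auto = true;
    s.gamma_ls = std::max(as<double>(pars["u_c"]), as<double>(pars["u_d"]));
  }
  s.eps_ls = as<double>(pars["eps"]);
  s.u_c = as<double>(pars["u_c"]);
  s.u_d = as<double>(pars["u_d"]);
  s.p_tol = pars.containsElementNamed("p_tol") ?
      as<double>(pars["p_tol"]) : 1e-10;
  classify_faces(g, s.u_c, s.u_d, s.fc);
  s.init_from(g);
  std::copy(u0.begin(), u0.end(), s.u.begin());
  std::copy(v0.begin(), v0.end(), s.v.begin());
  std::copy(p0.begin(), p0.end(), s.p.begin());
  std::copy(phi0.begin(), phi0.end(), s.phi.begin());
  s.t = t0;

  // recorded series
  std::vector<double> rec_t, rec_mass, rec_div, rec_pc, rec_pd, rec_umax,
      rec_influx, rec_outflux;
  // droplet component log: time, label, area_cells, cx, cy, attached
  std::vector<double> comp_rows;
  std::vector<int> lab;

  int pc_cell = probe_cells.size() > 0 ? probe_cells[0] : -1;
  int pd_cell = probe_cells.size() > 1 ? probe_cells[1] : -1;

  auto record = [&]() {
    double mass = 0;
    for (int k = 0; k < nx * ny; ++k)
      if (g.fluid[k]) mass += s.phi[k];
    mass *= h_m * h_m;
    double umax = 0;
    for (size_t k = 0; k < s.u.size(); ++k)
      if (s.fc.ukind[k] && std::fabs(s.u[k]) > umax) umax = std::fabs(s.u[k]);
    for (size_t k = 0; k < s.v.size(); ++k)
      if (s.fc.vkind[k] && std::fabs(s.v[k]) > umax) umax = std::fabs(s.v[k]);
    double influx = 0;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i)
        if (g.xtag[g.FX(i, j)] == TAG_IND && s.fc.ukind[g.FX(i, j)] == 2)
          influx += std::fabs(s.fc.ubc[g.FX(i, j)]) * h_m;
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (g.ytag[g.FY(i, j)] == TAG_IND && s.fc.vkind[g.FY(i, j)] == 2)
          influx += std::fabs(s.fc.vbc[g.FY(i, j)]) * h_m;
    // dispersed-phase volumetric outflow through outlet faces (2D flux)
    double outflux = 0;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        int id = g.FX(i, j);
        if (s.fc.ukind[id] != 3) continue;
        bool L = g.fl(i - 1, j);
        double uout = L ? s.u[id] : -s.u[id];
        double ph = L ? s.phi[g.C(i - 1, j)] : s.phi[g.C(i, j)];
        if (uout > 0) outflux += uout * ph * h_m;
      }
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = g.FY(i, j);
        if (s.fc.vkind[id] != 3) continue;
        bool B = g.fl(i, j - 1);
        double vout = B ? s.v[id] : -s.v[id];
        double ph = B ? s.phi[g.C(i, j - 1)] : s.phi[g.C(i, j)];
        if (vout > 0) outflux += vout * ph * h_m;
      }
    rec_outflux.push_back(outflux);
    rec_t.push_back(s.t);
    rec_mass.push_back(mass);
    rec_umax.push_back(umax);
    rec_influx.push_back(influx);
    rec_pc.push_back(pc_cell >= 0 ? s.p[pc_cell] : NA_REAL);
    rec_pd.push_back(pd_cell >= 0 ? s.p[pd_cell] : NA_REAL);
    rec_div.push_back(0.0);  // filled by caller of project below
    if (do_levelset) {
      int ncomp = label_components(g, s.phi, 0.5, lab);
      if (ncomp > 0) {
        // component stats; attachment = component contains a cell adjacent
        // to a dispersed inlet face
        std::vector<double> area(ncomp, 0), cx(ncomp, 0), cy(ncomp, 0);
        std::vector<int> att(ncomp, 0);
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            int L = lab[g.C(i, j)];
            if (!L) continue;
            area[L - 1] += 1;
            cx[L - 1] += (i + 0.5);
            cy[L - 1] += (j + 0.5);
            if (g.xtag[g.FX(i, j)] == TAG_IND ||
                g.xtag[g.FX(i + 1, j)] == TAG_IND ||
                g.ytag[g.FY(i, j)] == TAG_IND ||
                g.ytag[g.FY(i, j + 1)] == TAG_IND)
              att[L - 1] = 1;
          }
        for (int L = 0; L < ncomp; ++L) {
          comp_rows.push_back(s.t);
          comp_rows.push_back(L + 1);
          comp_rows.push_back(area[L]);
          comp_rows.push_back(cx[L] / area[L]);
          comp_rows.push_back(cy[L] / area[L]);
          comp_rows.push_back(att[L]);
        }
      }
    }
  };

  s.update_properties();
  record();

  int step = 0;
  double divmax_last = 0.0;
  double tim_csf = 0, tim_adv = 0, tim_visc = 0, tim_proj = 0;
  bool nan_abort = false;
  double dt = dt_fixed;
  while (s.t < t_end - 1e-15 && step < max_steps) {
    if (dt_fixed <= 0 && step % 8 == 0) dt = s.stable_dt(cfl_adv);
    double dt_use = std::min(dt, t_end - s.t);
    s.update_properties();
    if (do_momentum) {
      auto t1 = std::chrono::steady_clock::now();
      s.compute_surface_tension();
      auto t2 = std::chrono::steady_clock::now();
      s.advect_velocity(dt_use);
      auto t3 = std::chrono::steady_clock::now();
      s.viscous_solve(dt_use);
      auto t4 = std::chrono::steady_clock::now();
      divmax_last = s.project(dt_use);
      auto t5 = std::chrono::steady_clock::now();
      tim_csf += std::chrono::duration<double>(t2 - t1).count();
      tim_adv += std::chrono::duration<double>(t3 - t2).count();
      tim_visc += std::chrono::duration<double>(t4 - t3).count();
      tim_proj += std::chrono::duration<double>(t5 - t4).count();
    }
    if (do_levelset) s.levelset_step(dt_use, periodic_x);
    s.t += dt_use;
    ++step;
    if (step % record_every == 0 || s.t >= t_end - 1e-15) {
      // NaN guard
      double chk = 0;
      for (int k = 0; k < nx * ny; ++k) chk += s.phi[k];
      for (size_t k = 0; k < s.u.size(); ++k) chk += s.u[k];
      if (!std::isfinite(chk)) { nan_abort = true; break; }
      record();
      rec_div.back() = divmax_last;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix comp((int)comp_rows.size() / 6, 6);
  for (int r = 0; r < comp.nrow(); ++r)
    for (int c = 0; c < 6; ++c) comp(r, c) = comp_rows[r * 6 + c];
  colnames(comp) = CharacterVector::create("t", "label", "area_cells",
                                           "cx_cell", "cy_cell", "attached");
  return List::create(
    _["u"] = NumericVector(s.u.begin(), s.u.end()),
    _["v"] = NumericVector(s.v.begin(), s.v.end()),
    _["p"] = NumericVector(s.p.begin(), s.p.end()),
    _["phi"] = NumericVector(s.phi.begin(), s.phi.end()),
    _["t"] = s.t, _["steps"] = step, _["dt_last"] = dt,
    _["divmax"] = divmax_last, _["nan_abort"] = nan_abort,
    _["cg_iters"] = s.last_cg_iters,
    _["timing"] = NumericVector::create(
        _["csf"] = tim_csf, _["advect"] = tim_adv,
        _["viscous"] = tim_visc, _["project"] = tim_proj),
    _["series"] = DataFrame::create(
        _["t"] = rec_t, _["dispersed_area"] = rec_mass,
        _["u_max"] = rec_umax, _["div_max"] = rec_div,
        _["p_probe_c"] = rec_pc, _["p_probe_d"] = rec_pd,
        _["influx_d"] = rec_influx, _["outflux_d"] = rec_outflux),
    _["components"] = comp);
}

// [[Rcpp::export]]
List csf_force_cpp(IntegerVector fluid, IntegerVector xtag,
                   IntegerVector ytag, int nx, int ny, double h_m,
                   NumericVector phi0, double sigma, double theta) {
  Solver s;
  Grid g = grid_from_R(fluid, xtag, ytag, nx, ny, h_m);
  s.rho_c = s.rho_d = 1000; s.mu_c = s.mu_d = 1e-3;
  s.sigma = sigma; s.theta = theta; s.gamma_ls = 0; s.eps_ls = h_m;
  classify_faces(g, 0, 0, s.fc);
  s.init_from(g);
  std::copy(phi0.begin(), phi0.end(), s.phi.begin());
  fill_contact_ghosts(s.g, s.phi, theta);
  s.update_properties();
  s.compute_surface_tension();
  return List::create(
    _["Fx"] = NumericVector(s.Fx.begin(), s.Fx.end()),
    _["Fy"] = NumericVector(s.Fy.begin(), s.Fy.end()),
    _["kappa"] = NumericVector(s.kappa.begin(), s.kappa.end()));
}

// [[Rcpp::export]]
NumericVector contact_ghosts_cpp(IntegerVector fluid, IntegerVector xtag,
                                 IntegerVector ytag, int nx, int ny,
                                 double h_m, NumericVector phi0,
                                 double theta) {
  Grid g = grid_from_R(fluid, xtag, ytag, nx, ny, h_m);
  std::vector<double> phi(phi0.begin(), phi0.end());
  fill_contact_ghosts(g, phi, theta);
  return NumericVector(phi.begin(), phi.end());
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector fluid, int nx, int ny,
                                   NumericVector phi0, double level) {
  Grid g;
  g.nx = nx; g.ny = ny; g.h = 1.0;
  g.fluid.assign(fluid.begin(), fluid.end());
  g.xtag.assign((nx + 1) * ny, 0);
  g.ytag.assign(nx * (ny + 1), 0);
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<int> lab;
  label_components(g, phi, level, lab);
  return IntegerVector(lab.begin(), lab.end());
}
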