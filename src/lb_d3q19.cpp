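// D3Q19 lattice-Boltzmann engine with resolved squirmer bodies.
//
// BGK collision; Ladd bounce-back-on-links at body surfaces with a boundary
// velocity term that includes the squirmer tangential slip; half-way
// bounce-back no-slip walls at z = 0 and z = H (optional, else periodic);
// periodic x, y. Bodies are neutrally buoyant spheres advanced by
// Newton-Euler with gravity as an external force; node cover/uncover events
// exchange mass and momentum with the body and are book-kept exactly.
// Units: lattice spacing = time step = fluid rest density = 1; cs^2 = 1/3.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int CX[19] = {0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0};
static const int CY[19] = {0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1};
static const int CZ[19] = {0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1};
static const int OPP[19] = {0, 2, 1, 4, 3, 6, 5, 8, 7,10, 9,12,11,14,13,16,15,18,17};
static const double W[19] = {
  1.0/3,
  1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36};

static inline int wrap(int a, int n) { int r = a % n; return r < 0 ? r + n : r; }

static inline double mindiff(double a, double b, double L) {
  // minimum-image difference a-b on a periodic interval of length L
  double d = a - b;
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

struct Diag {
  double mass0 = 0, mass1 = 0;
  double p0[3] = {0,0,0}, p1[3] = {0,0,0};
  double to_bodies[3] = {0,0,0};       // momentum exchanged fluid -> bodies via links
  double to_walls[3] = {0,0,0};        // momentum exchanged fluid -> walls
  double bb_mass = 0;                  // mass removed by the velocity term of BB links
  double created_mass = 0, deleted_mass = 0;
  double created_mom[3] = {0,0,0}, deleted_mom[3] = {0,0,0};
  double fluid_force_imp[3] = {0,0,0};
  double body_impulse[3] = {0,0,0};    // all impulses actually applied to bodies
  bool blowup = false;
};

static void fluid_totals(const std::vector<double>& f, const std::vector<int>& mask,
                         int nnode, double* mass, double* p) {
  double m = 0, px = 0, py = 0, pz = 0;
  for (int n = 0; n < nnode; ++n) {
    if (mask[n] >= 0) continue;
    const double* fp = &f[(size_t)n * 19];
    for (int i = 0; i < 19; ++i) {
      m += fp[i];
      px += fp[i] * CX[i]; py += fp[i] * CY[i]; pz += fp[i] * CZ[i];
    }
  }
  *mass = m; p[0] = px; p[1] = py; p[2] = pz;
}

// slip velocity of the squirmer surface at unit outward normal rhat
static inline void slip_vec(const double* e, const double* rhat,
                            double B1, double B2, double* out) {
  double cth = e[0]*rhat[0] + e[1]*rhat[1] + e[2]*rhat[2];
  double amp = B1 + B2 * cth;
  out[0] = amp * (cth * rhat[0] - e[0]);
  out[1] = amp * (cth * rhat[1] - e[1]);
  out[2] = amp * (cth * rhat[2] - e[2]);
}

// recompute the solid mask from body positions; nodes at (i+0.5, j+0.5, k+0.5)
static void compute_mask(std::vector<int>& mask, int Nx, int Ny, int Nz,
                         const NumericMatrix& B, double Rp, int walls_z) {
  std::fill(mask.begin(), mask.end(), -1);
  double R2 = Rp * Rp;
  int nb = B.nrow();
  for (int b = 0; b < nb; ++b) {
    double X = B(b,0), Y = B(b,1), Z = B(b,2);
    int i0 = (int)std::floor(X - Rp - 1), i1 = (int)std::ceil(X + Rp + 1);
    int j0 = (int)std::floor(Y - Rp - 1), j1 = (int)std::ceil(Y + Rp + 1);
    int k0 = (int)std::floor(Z - Rp - 1), k1 = (int)std::ceil(Z + Rp + 1);
    if (walls_z) { k0 = std::max(0, k0); k1 = std::min(Nz - 1, k1); }
    for (int k = k0; k <= k1; ++k) {
      double dz = walls_z ? (k + 0.5) - Z : mindiff(k + 0.5, Z, Nz);
      int kk = walls_z ? k : wrap(k, Nz);
      for (int j = j0; j <= j1; ++j) {
        double dy = mindiff(j + 0.5, Y, Ny);
        int jj = wrap(j, Ny);
        for (int i = i0; i <= i1; ++i) {
          double dx = mindiff(i + 0.5, X, Nx);
          if (dx*dx + dy*dy + dz*dz < R2) {
            int ii = wrap(i, Nx);
            mask[((size_t)kk * Ny + jj) * Nx + ii] = b;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
IntegerVector lb_make_mask(int Nx, int Ny, int Nz, NumericMatrix bodies, double Rp,
                           int walls_z = 1) {
  std::vector<int> mask((size_t)Nx * Ny * Nz);
  compute_mask(mask, Nx, Ny, Nz, bodies, Rp, walls_z);
  return IntegerVector(mask.begin(), mask.end());
}

// [[Rcpp::export]]
NumericVector lb_equilibrium(int Nx, int Ny, int Nz, NumericVector rho,
                             NumericVector ux, NumericVector uy, NumericVector uz) {
  size_t nnode = (size_t)Nx * Ny * Nz;
  NumericVector f(nnode * 19);
  bool scal = rho.size() == 1;
  for (size_t n = 0; n < nnode; ++n) {
    double r = scal ? rho[0] : rho[n];
    double vx = ux.size() == 1 ? ux[0] : ux[n];
    double vy = uy.size() == 1 ? uy[0] : uy[n];
    double vz = uz.size() == 1 ? uz[0] : uz[n];
    double usq = vx*vx + vy*vy + vz*vz;
    for (int i = 0; i < 19; ++i) {
      double cu = CX[i]*vx + CY[i]*vy + CZ[i]*vz;
      f[n*19 + i] = W[i] * r * (1.0 + 3.0*cu + 4.5*cu*cu - 1.5*usq);
    }
  }
  return f;
}

// [[Rcpp::export]]
List lb_macroscopics(NumericVector f, IntegerVector mask, int Nx, int Ny, int Nz) {
  size_t nnode = (size_t)Nx * Ny * Nz;
  NumericVector rho(nnode), ux(nnode), uy(nnode), uz(nnode);
  for (size_t n = 0; n < nnode; ++n) {
    if (mask[n] >= 0) { rho[n] = NA_REAL; ux[n] = NA_REAL; uy[n] = NA_REAL; uz[n] = NA_REAL; continue; }
    double r = 0, px = 0, py = 0, pz = 0;
    for (int i = 0; i < 19; ++i) {
      double fi = f[n*19 + i];
      r += fi; px += fi*CX[i]; py += fi*CY[i]; pz += fi*CZ[i];
    }
    rho[n] = r;
    ux[n] = px / r; uy[n] = py / r; uz[n] = pz / r;
  }
  return List::create(_["rho"] = rho, _["ux"] = ux, _["uy"] = uy, _["uz"] = uz);
}

// per-slab moments of the fluid velocity: n, sum u, sum |u|^2
// [[Rcpp::export]]
NumericMatrix lb_slab_moments(NumericVector f, IntegerVector mask,
                              int Nx, int Ny, int Nz) {
  NumericMatrix M(Nz, 5);
  for (int k = 0; k < Nz; ++k) {
    double cnt = 0, sx = 0, sy = 0, sz = 0, s2 = 0;
    for (int j = 0; j < Ny; ++j) for (int i = 0; i < Nx; ++i) {
      size_t n = ((size_t)k * Ny + j) * Nx + i;
      if (mask[n] >= 0) continue;
      double r = 0, px = 0, py = 0, pz = 0;
      for (int q = 0; q < 19; ++q) {
        double fq = f[n*19 + q];
        r += fq; px += fq*CX[q]; py += fq*CY[q]; pz += fq*CZ[q];
      }
      double vx = px/r, vy = py/r, vz = pz/r;
      cnt += 1; sx += vx; sy += vy; sz += vz; s2 += vx*vx + vy*vy + vz*vz;
    }
    M(k,0) = cnt; M(k,1) = sx; M(k,2) = sy; M(k,3) = sz; M(k,4) = s2;
  }
  return M;
}

// [[Rcpp::export]]
List lb_run_chunk(NumericVector f_in, IntegerVector mask_in, NumericMatrix bodies_in,
                  IntegerVector mobile, int Nx, int Ny, int Nz,
                  double tau_lb, double B1, double B2, double Rp, double Fg,
                  double spring_k, double gap_on, int walls_z,
                  NumericVector fluid_force, int nsteps) {
  size_t nnode = (size_t)Nx * Ny * Nz;
  std::vector<double> f(f_in.begin(), f_in.end());
  std::vector<double> fnew(nnode * 19, 0.0);
  std::vector<int> mask(mask_in.begin(), mask_in.end());
  NumericMatrix B = clone(bodies_in);
  int nb = B.nrow();
  double omega = 1.0 / tau_lb;
  double mbody = 4.0 / 3.0 * M_PI * Rp * Rp * Rp;   // rho0 = 1, neutrally buoyant
  double inert = 0.4 * mbody * Rp * Rp;
  double gx = fluid_force.size() ? fluid_force[0] : 0.0;
  double gy = fluid_force.size() > 1 ? fluid_force[1] : 0.0;
  double gz = fluid_force.size() > 2 ? fluid_force[2] : 0.0;
  bool has_g = gx != 0 || gy != 0 || gz != 0;

  Diag d;
  fluid_totals(f, mask, (int)nnode, &d.mass0, d.p0);

  std::vector<double> Fh(3 * nb), Th(3 * nb);
  std::vector<int> old_mask(nnode);

  for (int step = 0; step < nsteps; ++step) {
    std::fill(Fh.begin(), Fh.end(), 0.0);
    std::fill(Th.begin(), Th.end(), 0.0);
    std::fill(fnew.begin(), fnew.end(), 0.0);

    for (int k = 0; k < Nz; ++k)
    for (int j = 0; j < Ny; ++j)
    for (int i = 0; i < Nx; ++i) {
      size_t n = ((size_t)k * Ny + j) * Nx + i;
      if (mask[n] >= 0) continue;
      double* fp = &f[n * 19];
      double r = 0, px = 0, py = 0, pz = 0;
      for (int q = 0; q < 19; ++q) {
        r += fp[q]; px += fp[q]*CX[q]; py += fp[q]*CY[q]; pz += fp[q]*CZ[q];
      }
      if (!(r > 0) || !std::isfinite(r)) { d.blowup = true; }
      double vx = px/r, vy = py/r, vz = pz/r;
      double usq = vx*vx + vy*vy + vz*vz;
      double fstar[19];
      for (int q = 0; q < 19; ++q) {
        double cu = CX[q]*vx + CY[q]*vy + CZ[q]*vz;
        double feq = W[q] * r * (1.0 + 3.0*cu + 4.5*cu*cu - 1.5*usq);
        fstar[q] = fp[q] + omega * (feq - fp[q]);
        if (has_g) fstar[q] += 3.0 * W[q] * (CX[q]*gx + CY[q]*gy + CZ[q]*gz);
      }
      if (has_g) {
        d.fluid_force_imp[0] += gx; d.fluid_force_imp[1] += gy; d.fluid_force_imp[2] += gz;
      }
      // streaming with boundary handling
      for (int q = 0; q < 19; ++q) {
        int ti = i + CX[q], tj = j + CY[q], tk = k + CZ[q];
        bool at_wall = walls_z && (tk < 0 || tk >= Nz);
        if (at_wall) {
          fnew[n*19 + OPP[q]] += fstar[q];
          d.to_walls[0] += 2.0 * fstar[q] * CX[q];
          d.to_walls[1] += 2.0 * fstar[q] * CY[q];
          d.to_walls[2] += 2.0 * fstar[q] * CZ[q];
          continue;
        }
        int wi = wrap(ti, Nx), wj = wrap(tj, Ny), wk = wrap(tk, Nz);
        size_t t = ((size_t)wk * Ny + wj) * Nx + wi;
        int b = mask[t];
        if (b < 0) {
          fnew[t*19 + q] += fstar[q];
        } else {
          // Ladd bounce-back on the link with boundary velocity term
          double xb = i + 0.5 + 0.5*CX[q];
          double yb = j + 0.5 + 0.5*CY[q];
          double zb = k + 0.5 + 0.5*CZ[q];
          double rx = mindiff(xb, B(b,0), Nx);
          double ry = mindiff(yb, B(b,1), Ny);
          double rz = walls_z ? zb - B(b,2) : mindiff(zb, B(b,2), Nz);
          double ub[3];
          ub[0] = B(b,3) + B(b,7)*rz - B(b,8)*ry;
          ub[1] = B(b,4) + B(b,8)*rx - B(b,6)*rz;
          ub[2] = B(b,5) + B(b,6)*ry - B(b,7)*rx;
          if (B1 != 0.0 || B2 != 0.0) {
            double rn = std::sqrt(rx*rx + ry*ry + rz*rz);
            if (rn > 1e-12) {
              double rhat[3] = {rx/rn, ry/rn, rz/rn};
              double e[3] = {B(b,9), B(b,10), B(b,11)};
              double us[3];
              slip_vec(e, rhat, B1, B2, us);
              ub[0] += us[0]; ub[1] += us[1]; ub[2] += us[2];
            }
          }
          double cub = CX[q]*ub[0] + CY[q]*ub[1] + CZ[q]*ub[2];
          double corr = 6.0 * W[q] * r * cub;      // 2 w rho (c.u_b)/cs^2
          fnew[n*19 + OPP[q]] += fstar[q] - corr;
          d.bb_mass += corr;
          double dpx = (2.0*fstar[q] - corr) * CX[q];
          double dpy = (2.0*fstar[q] - corr) * CY[q];
          double dpz = (2.0*fstar[q] - corr) * CZ[q];
          Fh[3*b+0] += dpx; Fh[3*b+1] += dpy; Fh[3*b+2] += dpz;
          Th[3*b+0] += ry*dpz - rz*dpy;
          Th[3*b+1] += rz*dpx - rx*dpz;
          Th[3*b+2] += rx*dpy - ry*dpx;
          d.to_bodies[0] += dpx; d.to_bodies[1] += dpy; d.to_bodies[2] += dpz;
        }
      }
    }
    std::swap(f, fnew);

    if (nb > 0) {
      // contact guard: short-range Hookean repulsion, bodies and walls
      std::vector<double> Frep(3 * nb, 0.0);
      for (int a = 0; a < nb; ++a) for (int b2 = a + 1; b2 < nb; ++b2) {
        double dx = mindiff(B(a,0), B(b2,0), Nx);
        double dy = mindiff(B(a,1), B(b2,1), Ny);
        double dz = walls_z ? B(a,2) - B(b2,2) : mindiff(B(a,2), B(b2,2), Nz);
        double dist = std::sqrt(dx*dx + dy*dy + dz*dz);
        double over = 2.0*Rp + gap_on - dist;
        if (over > 0 && dist > 1e-9) {
          double fmag = spring_k * over / dist;
          Frep[3*a+0] += fmag*dx; Frep[3*a+1] += fmag*dy; Frep[3*a+2] += fmag*dz;
          Frep[3*b2+0] -= fmag*dx; Frep[3*b2+1] -= fmag*dy; Frep[3*b2+2] -= fmag*dz;
        }
      }
      if (walls_z) {
        for (int b = 0; b < nb; ++b) {
          double glo = B(b,2) - Rp;          // wall plane z = 0
          if (glo < gap_on) Frep[3*b+2] += spring_k * (gap_on - glo);
          double ghi = Nz - B(b,2) - Rp;     // wall plane z = H = Nz
          if (ghi < gap_on) Frep[3*b+2] -= spring_k * (gap_on - ghi);
        }
      }
      for (int b = 0; b < nb; ++b) {
        if (mobile[b] == 1) {
          double Fx = 0.5*(Fh[3*b+0] + B(b,12)) + Frep[3*b+0];
          double Fy = 0.5*(Fh[3*b+1] + B(b,13)) + Frep[3*b+1];
          double Fz = 0.5*(Fh[3*b+2] + B(b,14)) + Frep[3*b+2] - Fg;
          double Tx = 0.5*(Th[3*b+0] + B(b,15));
          double Ty = 0.5*(Th[3*b+1] + B(b,16));
          double Tz = 0.5*(Th[3*b+2] + B(b,17));
          B(b,3) += Fx / mbody; B(b,4) += Fy / mbody; B(b,5) += Fz / mbody;
          B(b,6) += Tx / inert; B(b,7) += Ty / inert; B(b,8) += Tz / inert;
          d.body_impulse[0] += Fx; d.body_impulse[1] += Fy; d.body_impulse[2] += Fz;
          // advance position and orientation
          B(b,0) += B(b,3); B(b,1) += B(b,4); B(b,2) += B(b,5);
          B(b,0) = B(b,0) - Nx * std::floor(B(b,0) / Nx);
          B(b,1) = B(b,1) - Ny * std::floor(B(b,1) / Ny);
          if (!walls_z) B(b,2) = B(b,2) - Nz * std::floor(B(b,2) / Nz);
          double ex = B(b,9), ey = B(b,10), ez = B(b,11);
          double nex = ex + (B(b,7)*ez - B(b,8)*ey);
          double ney = ey + (B(b,8)*ex - B(b,6)*ez);
          double nez = ez + (B(b,6)*ey - B(b,7)*ex);
          double nn = std::sqrt(nex*nex + ney*ney + nez*nez);
          B(b,9) = nex/nn; B(b,10) = ney/nn; B(b,11) = nez/nn;
        } else if (mobile[b] == 2) {
          B(b,0) += B(b,3); B(b,1) += B(b,4); B(b,2) += B(b,5);
          B(b,0) = B(b,0) - Nx * std::floor(B(b,0) / Nx);
          B(b,1) = B(b,1) - Ny * std::floor(B(b,1) / Ny);
          if (!walls_z) B(b,2) = B(b,2) - Nz * std::floor(B(b,2) / Nz);
        }
        B(b,12) = Fh[3*b+0]; B(b,13) = Fh[3*b+1]; B(b,14) = Fh[3*b+2];
        B(b,15) = Th[3*b+0]; B(b,16) = Th[3*b+1]; B(b,17) = Th[3*b+2];
      }

      // mask refresh with cover/uncover bookkeeping
      std::copy(mask.begin(), mask.end(), old_mask.begin());
      compute_mask(mask, Nx, Ny, Nz, B, Rp, walls_z);
      for (int k = 0; k < Nz; ++k)
      for (int j = 0; j < Ny; ++j)
      for (int i = 0; i < Nx; ++i) {
        size_t n = ((size_t)k * Ny + j) * Nx + i;
        if (old_mask[n] < 0 && mask[n] >= 0) {
          // node covered: its fluid mass and momentum go to the body
          int b = mask[n];
          double* fp = &f[n*19];
          double m = 0, px = 0, py = 0, pz = 0;
          for (int q = 0; q < 19; ++q) {
            m += fp[q]; px += fp[q]*CX[q]; py += fp[q]*CY[q]; pz += fp[q]*CZ[q];
            fp[q] = 0.0;
          }
          d.deleted_mass += m;
          d.deleted_mom[0] += px; d.deleted_mom[1] += py; d.deleted_mom[2] += pz;
          if (mobile[b] == 1) {
            B(b,3) += px / mbody; B(b,4) += py / mbody; B(b,5) += pz / mbody;
            d.body_impulse[0] += px; d.body_impulse[1] += py; d.body_impulse[2] += pz;
          }
        } else if (old_mask[n] >= 0 && mask[n] < 0) {
          // node uncovered: refill at the local body surface velocity
          int b = old_mask[n];
          double rsum = 0; int rcnt = 0;
          for (int q = 1; q < 19; ++q) {
            int ti = wrap(i + CX[q], Nx), tj = wrap(j + CY[q], Ny), tk = k + CZ[q];
            if (tk < 0 || tk >= Nz) { if (walls_z) continue; tk = wrap(tk, Nz); }
            size_t t = ((size_t)tk * Ny + tj) * Nx + ti;
            if (old_mask[t] < 0 && mask[t] < 0) {
              double rr = 0;
              for (int q2 = 0; q2 < 19; ++q2) rr += f[t*19 + q2];
              rsum += rr; rcnt++;
            }
          }
          double rho0 = rcnt ? rsum / rcnt : 1.0;
          double rx = mindiff(i + 0.5, B(b,0), Nx);
          double ry = mindiff(j + 0.5, B(b,1), Ny);
          double rz = walls_z ? (k + 0.5) - B(b,2) : mindiff(k + 0.5, B(b,2), Nz);
          double ub[3];
          ub[0] = B(b,3) + B(b,7)*rz - B(b,8)*ry;
          ub[1] = B(b,4) + B(b,8)*rx - B(b,6)*rz;
          ub[2] = B(b,5) + B(b,6)*ry - B(b,7)*rx;
          double usq = ub[0]*ub[0] + ub[1]*ub[1] + ub[2]*ub[2];
          double* fp = &f[n*19];
          for (int q = 0; q < 19; ++q) {
            double cu = CX[q]*ub[0] + CY[q]*ub[1] + CZ[q]*ub[2];
            fp[q] = W[q] * rho0 * (1.0 + 3.0*cu + 4.5*cu*cu - 1.5*usq);
          }
          d.created_mass += rho0;
          d.created_mom[0] += rho0*ub[0]; d.created_mom[1] += rho0*ub[1]; d.created_mom[2] += rho0*ub[2];
          if (mobile[b] == 1) {
            B(b,3) -= rho0*ub[0] / mbody; B(b,4) -= rho0*ub[1] / mbody; B(b,5) -= rho0*ub[2] / mbody;
            d.body_impulse[0] -= rho0*ub[0]; d.body_impulse[1] -= rho0*ub[1]; d.body_impulse[2] -= rho0*ub[2];
          }
        }
      }
    }
    if (d.blowup) stop("lattice-Boltzmann populations diverged (negative or non-finite density); reduce velocities or forces");
  }

  fluid_totals(f, mask, (int)nnode, &d.mass1, d.p1);

  List diag = List::create(
    _["mass_start"] = d.mass0, _["mass_end"] = d.mass1,
    _["p_start"] = NumericVector::create(d.p0[0], d.p0[1], d.p0[2]),
    _["p_end"] = NumericVector::create(d.p1[0], d.p1[1], d.p1[2]),
    _["to_bodies"] = NumericVector::create(d.to_bodies[0], d.to_bodies[1], d.to_bodies[2]),
    _["to_walls"] = NumericVector::create(d.to_walls[0], d.to_walls[1], d.to_walls[2]),
    _["bb_mass"] = d.bb_mass,
    _["created_mass"] = d.created_mass, _["deleted_mass"] = d.deleted_mass,
    _["created_mom"] = NumericVector::create(d.created_mom[0], d.created_mom[1], d.created_mom[2]),
    _["deleted_mom"] = NumericVector::create(d.deleted_mom[0], d.deleted_mom[1], d.deleted_mom[2]),
    _["fluid_force_impulse"] = NumericVector::create(d.fluid_force_imp[0], d.fluid_force_imp[1], d.fluid_force_imp[2]),
    _["body_impulse"] = NumericVector::create(d.body_impulse[0], d.body_impulse[1], d.body_impulse[2]));

  return List::create(_["f"] = NumericVector(f.begin(), f.end()),
                      _["mask"] = IntegerVector(mask.begin(), mask.end()),
                      _["bodies"] = B, _["diag"] = diag);
}
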