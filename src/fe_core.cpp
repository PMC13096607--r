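// Core assembly and Newton solve for the axisymmetric fibril-reinforced
// poroviscoelastic finite-element model (bilinear u / bilinear p quads,
// backward-Euler Biot time stepping, rigid frictionless platen as a single
// shared axial degree of freedom handled as a bordered row/column around a
// banded LAPACK factorisation).
//
// All quantities here are SI (m, Pa, s); unit conversion happens in R.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
#include <cmath>
#include <numeric>
#include <vector>

using namespace Rcpp;

namespace {

struct Material {
  double E_nf, nu, mu_s, lam_s;   // nonfibrillar matrix (Pa)
  double E_f0, E_feps, eta;       // fibril network (Pa, Pa, Pa s)
  double k0, M;                   // permeability law
  int small_strain;
};

struct FemData {
  int nn, nel, ndof, bw, ndir;
  const double* Xr;       // reference nodal coords (m), length nn each
  const double* Xz;
  const int* conn;        // nel x 4, column-major from R
  const int* dof_ur;      // per node: >=0 dof id, -1 fixed
  const int* dof_uz;      // >=0 dof id, -1 fixed, -2 tied to platen
  const int* dof_p;       // >=0 dof id, -1 fixed (p = 0)
  const double* dirs;     // ndir x 3 (r, z, theta), column-major
  const double* wts;      // ndir
  double stab_alpha;
  Material mat;
};

const double GP = 0.5773502691896258;
const double gp_xi[4]  = {-GP,  GP,  GP, -GP};
const double gp_eta[4] = {-GP, -GP,  GP,  GP};

inline void shape(double xi, double eta, double* N, double* dNxi,
                  double* dNeta) {
  N[0] = 0.25 * (1 - xi) * (1 - eta);
  N[1] = 0.25 * (1 + xi) * (1 - eta);
  N[2] = 0.25 * (1 + xi) * (1 + eta);
  N[3] = 0.25 * (1 - xi) * (1 + eta);
  dNxi[0] = -0.25 * (1 - eta); dNeta[0] = -0.25 * (1 - xi);
  dNxi[1] =  0.25 * (1 - eta); dNeta[1] = -0.25 * (1 + xi);
  dNxi[2] =  0.25 * (1 + eta); dNeta[2] =  0.25 * (1 - xi);
  dNxi[3] = -0.25 * (1 + eta); dNeta[3] =  0.25 * (1 + xi);
}

// Element residual. Local unknowns: ur[4], uz[4], pp[4]; old displacements
// give J_old and the fibril strain at the start of the step; q_old are the
// Maxwell overstresses per Gauss point x direction. If q_out is non-null
// the backward-Euler updated overstresses are written there.
void elem_residual(const FemData& fd, int e,
                   const double* ur, const double* uz, const double* pp,
                   const double* ur_old, const double* uz_old,
                   const double* pp_old,
                   const double* q_old, double dt,
                   double* res, double* q_out) {
  const Material& m = fd.mat;
  double Xr[4], Xz[4];
  for (int a = 0; a < 4; ++a) {
    int n = fd.conn[e + a * fd.nel];
    Xr[a] = fd.Xr[n];
    Xz[a] = fd.Xz[n];
  }
  for (int i = 0; i < 12; ++i) res[i] = 0.0;

  double pgps[4], pgps_old[4], dvs[4], Ngp[4][4];  // stabilisation data

  for (int g = 0; g < 4; ++g) {
    double N[4], dNxi[4], dNeta[4];
    shape(gp_xi[g], gp_eta[g], N, dNxi, dNeta);
    // reference Jacobian
    double J00 = 0, J01 = 0, J10 = 0, J11 = 0, Rgp = 0;
    for (int a = 0; a < 4; ++a) {
      J00 += Xr[a] * dNxi[a];  J01 += Xr[a] * dNeta[a];
      J10 += Xz[a] * dNxi[a];  J11 += Xz[a] * dNeta[a];
      Rgp += N[a] * Xr[a];
    }
    double detref = J00 * J11 - J01 * J10;
    double dNdX[4][2];
    for (int a = 0; a < 4; ++a) {
      dNdX[a][0] = ( J11 * dNxi[a] - J10 * dNeta[a]) / detref;
      dNdX[a][1] = (-J01 * dNxi[a] + J00 * dNeta[a]) / detref;
    }
    // displacement gradients w.r.t. reference coords
    double H00 = 0, H01 = 0, H10 = 0, H11 = 0, urg = 0;
    double O00 = 0, O01 = 0, O10 = 0, O11 = 0, urgo = 0;
    for (int a = 0; a < 4; ++a) {
      H00 += ur[a] * dNdX[a][0]; H01 += ur[a] * dNdX[a][1];
      H10 += uz[a] * dNdX[a][0]; H11 += uz[a] * dNdX[a][1];
      urg += N[a] * ur[a];
      O00 += ur_old[a] * dNdX[a][0]; O01 += ur_old[a] * dNdX[a][1];
      O10 += uz_old[a] * dNdX[a][0]; O11 += uz_old[a] * dNdX[a][1];
      urgo += N[a] * ur_old[a];
    }

    double J, J_old, r_int, detcur, dNdx[4][2];
    double srr = 0, szz = 0, sth = 0, srz = 0;   // effective Cauchy stress
    double F00 = 1, F01 = 0, F10 = 0, F11 = 1, Fth = 1;
    double F00o = 1, F01o = 0, F10o = 0, F11o = 1, Ftho = 1;

    if (m.small_strain) {
      double err = H00, ezz = H11, eth = urg / Rgp;
      double erz = 0.5 * (H01 + H10);
      double tr = err + ezz + eth;
      J = 1.0 + tr;
      J_old = 1.0 + O00 + O11 + urgo / Rgp;
      srr = m.lam_s * tr + 2 * m.mu_s * err;
      szz = m.lam_s * tr + 2 * m.mu_s * ezz;
      sth = m.lam_s * tr + 2 * m.mu_s * eth;
      srz = 2 * m.mu_s * erz;
      r_int = Rgp;
      detcur = detref;
      for (int a = 0; a < 4; ++a) {
        dNdx[a][0] = dNdX[a][0];
        dNdx[a][1] = dNdX[a][1];
      }
    } else {
      F00 = 1 + H00; F01 = H01; F10 = H10; F11 = 1 + H11;
      Fth = 1 + urg / Rgp;
      double det2 = F00 * F11 - F01 * F10;
      J = det2 * Fth;
      F00o = 1 + O00; F01o = O01; F10o = O10; F11o = 1 + O11;
      Ftho = 1 + urgo / Rgp;
      J_old = (F00o * F11o - F01o * F10o) * Ftho;
      if (J <= 0.0 || det2 <= 0.0) {  // inverted element: poison residual
        for (int i = 0; i < 12; ++i) res[i] = 1e30;
        return;
      }
      // current configuration geometry
      double xr[4], xz[4];
      for (int a = 0; a < 4; ++a) { xr[a] = Xr[a] + ur[a]; xz[a] = Xz[a] + uz[a]; }
      double C00 = 0, C01 = 0, C10 = 0, C11 = 0;
      r_int = 0;
      for (int a = 0; a < 4; ++a) {
        C00 += xr[a] * dNxi[a]; C01 += xr[a] * dNeta[a];
        C10 += xz[a] * dNxi[a]; C11 += xz[a] * dNeta[a];
        r_int += N[a] * xr[a];
      }
      detcur = C00 * C11 - C01 * C10;
      for (int a = 0; a < 4; ++a) {
        dNdx[a][0] = ( C11 * dNxi[a] - C10 * dNeta[a]) / detcur;
        dNdx[a][1] = (-C01 * dNxi[a] + C00 * dNeta[a]) / detcur;
      }
      // compressible Neo-Hookean matrix
      double B00 = F00 * F00 + F01 * F01;
      double B11 = F10 * F10 + F11 * F11;
      double B01 = F00 * F10 + F01 * F11;
      double Bth = Fth * Fth;
      double lnJ = std::log(J);
      srr = m.mu_s / J * (B00 - 1) + m.lam_s / J * lnJ;
      szz = m.mu_s / J * (B11 - 1) + m.lam_s / J * lnJ;
      sth = m.mu_s / J * (Bth - 1) + m.lam_s / J * lnJ;
      srz = m.mu_s / J * B01;
    }

    // tension-only viscoelastic fibril network
    if (m.E_f0 > 0 || m.E_feps > 0) {
      for (int d = 0; d < fd.ndir; ++d) {
        double ar = fd.dirs[d], az = fd.dirs[d + fd.ndir],
               at = fd.dirs[d + 2 * fd.ndir];
        double eps_f, eps_o, mr, mz, mt;
        if (m.small_strain) {
          eps_f = ar * ar * H00 + az * az * H11 + at * at * (urg / Rgp) +
                  ar * az * (H01 + H10);
          eps_o = ar * ar * O00 + az * az * O11 + at * at * (urgo / Rgp) +
                  ar * az * (O01 + O10);
          mr = ar; mz = az; mt = at;
        } else {
          double fr = F00 * ar + F01 * az;
          double fz = F10 * ar + F11 * az;
          double ft = Fth * at;
          double lam = std::sqrt(fr * fr + fz * fz + ft * ft);
          eps_f = std::log(lam);
          mr = fr / lam; mz = fz / lam; mt = ft / lam;
          double fro = F00o * ar + F01o * az;
          double fzo = F10o * ar + F11o * az;
          double fto = Ftho * at;
          eps_o = std::log(std::sqrt(fro * fro + fzo * fzo + fto * fto));
        }
        double qo = q_old[g * fd.ndir + d];
        double qn = 0.0, sf = 0.0;
        if (eps_f > 0) {
          double Etan = m.E_f0 + m.E_feps * eps_f;
          double deps = eps_f - (eps_o > 0 ? eps_o : 0.0);
          // exponential map: exact for the Maxwell ODE over the step;
          // expm1 keeps the small-dt limit at full precision
          double xrel = dt * Etan / m.eta;
          qn = qo * std::exp(-xrel) -
            (m.eta * deps / dt) * std::expm1(-xrel);
          double seq = m.E_f0 * eps_f + 0.5 * m.E_feps * eps_f * eps_f;
          sf = seq + qn;
          if (sf < 0) { sf = 0.0; qn = -seq; }  // tension-only: no push
          const double eps_s = 1e-4;            // smooth recruitment
          if (eps_f < eps_s) {
            double sr = eps_f / eps_s;
            sf *= sr * sr * (3.0 - 2.0 * sr);
          }
        }
        if (q_out) q_out[g * fd.ndir + d] = qn;
        if (sf != 0.0) {
          double w = fd.wts[d] * sf;
          srr += w * mr * mr;
          szz += w * mz * mz;
          sth += w * mt * mt;
          srz += w * mr * mz;
          // m_r m_t and m_z m_t shear components cancel over the +/-
          // symmetric direction pairs of the layout; not assembled.
        }
      }
    } else if (q_out) {
      for (int d = 0; d < fd.ndir; ++d) q_out[g * fd.ndir + d] = 0.0;
    }

    // pore pressure and total stress
    double pg = 0, gpr = 0, gpz = 0, pgo = 0;
    for (int a = 0; a < 4; ++a) {
      pg += N[a] * pp[a];
      pgo += N[a] * pp_old[a];
      gpr += pp[a] * dNdx[a][0];
      gpz += pp[a] * dNdx[a][1];
    }
    double trr = srr - pg, tzz = szz - pg, tth = sth - pg, trz = srz;

    double dv = 2.0 * M_PI * r_int * detcur;   // unit Gauss weights
    double kperm = m.k0 * std::pow(J, m.M);

    for (int a = 0; a < 4; ++a) {
      res[a]     += (dNdx[a][0] * trr + dNdx[a][1] * trz +
                     N[a] / r_int * tth) * dv;
      res[4 + a] += (dNdx[a][0] * trz + dNdx[a][1] * tzz) * dv;
      res[8 + a] += ((J - J_old) / (dt * J) * N[a] +
                     kperm * (gpr * dNdx[a][0] + gpz * dNdx[a][1])) * dv;
      Ngp[g][a] = N[a];
    }
    pgps[g] = pg;
    pgps_old[g] = pgo;
    dvs[g] = dv;
  }

  // local pressure-projection stabilisation of the equal-order pair:
  // artificial storage (alpha / mu_s) d(p - pbar)/dt on the pressure
  // fluctuation. Acting on the rate keeps the scheme convergent under
  // time-step refinement (the fluctuation contribution telescopes).
  if (fd.stab_alpha > 0) {
    double V = 0, pbar = 0, pbar_o = 0, Nbar[4] = {0, 0, 0, 0};
    for (int g = 0; g < 4; ++g) {
      V += dvs[g];
      pbar += pgps[g] * dvs[g];
      pbar_o += pgps_old[g] * dvs[g];
      for (int a = 0; a < 4; ++a) Nbar[a] += Ngp[g][a] * dvs[g];
    }
    pbar /= V;
    pbar_o /= V;
    for (int a = 0; a < 4; ++a) Nbar[a] /= V;
    double tau = fd.stab_alpha / (m.mu_s * dt);
    for (int g = 0; g < 4; ++g) {
      double fluc = (pgps[g] - pbar) - (pgps_old[g] - pbar_o);
      for (int a = 0; a < 4; ++a)
        res[8 + a] += tau * fluc * (Ngp[g][a] - Nbar[a]) * dvs[g];
    }
  }
}

// Gather local nodal unknowns for element e from the packed dof vector
// (length ndof + 1; last entry is the platen axial displacement).
void gather(const FemData& fd, int e, const double* x,
            double* ur, double* uz, double* pp) {
  for (int a = 0; a < 4; ++a) {
    int n = fd.conn[e + a * fd.nel];
    int du = fd.dof_ur[n], dz = fd.dof_uz[n], dp = fd.dof_p[n];
    ur[a] = du >= 0 ? x[du] : 0.0;
    uz[a] = dz >= 0 ? x[dz] : (dz == -2 ? x[fd.ndof] : 0.0);
    pp[a] = dp >= 0 ? x[dp] : 0.0;
  }
}

FemData unpack(List fem) {
  FemData fd;
  NumericMatrix nodes = fem["nodes_m"];
  IntegerMatrix conn = fem["conn0"];
  fd.nn = nodes.nrow();
  fd.nel = conn.nrow();
  fd.ndof = as<int>(fem["n_dof"]);
  fd.bw = as<int>(fem["bw"]);
  fd.Xr = &nodes(0, 0);
  fd.Xz = &nodes(0, 1);
  fd.conn = &conn(0, 0);
  IntegerVector dur = fem["dof_ur"], duz = fem["dof_uz"], dp = fem["dof_p"];
  fd.dof_ur = &dur[0]; fd.dof_uz = &duz[0]; fd.dof_p = &dp[0];
  NumericMatrix dirs = fem["dirs"];
  NumericVector wts = fem["dir_wts"];
  fd.ndir = dirs.nrow();
  fd.dirs = &dirs(0, 0);
  fd.wts = &wts[0];
  fd.stab_alpha = as<double>(fem["stab_alpha"]);
  List mat = fem["mat_si"];
  fd.mat.E_nf = as<double>(mat["E_nf"]);
  fd.mat.nu = as<double>(mat["nu"]);
  fd.mat.mu_s = fd.mat.E_nf / (2 * (1 + fd.mat.nu));
  fd.mat.lam_s = fd.mat.E_nf * fd.mat.nu /
    ((1 + fd.mat.nu) * (1 - 2 * fd.mat.nu));
  fd.mat.E_f0 = as<double>(mat["E_f0"]);
  fd.mat.E_feps = as<double>(mat["E_feps"]);
  fd.mat.eta = as<double>(mat["eta"]);
  fd.mat.k0 = as<double>(mat["k0"]);
  fd.mat.M = as<double>(mat["M"]);
  fd.mat.small_strain = as<int>(fem["small_strain"]);
  return fd;
}

// Assemble global residual; optionally the banded Jacobian (element-level
// forward differences) and updated fibril overstresses.
void assemble(const FemData& fd, const double* x, const double* x_old,
              const double* q_old, double dt, double Fext,
              std::vector<double>& R,
              std::vector<double>* AB, std::vector<double>* bcol,
              std::vector<double>* crow, double* dcorner,
              double* q_new) {
  int n = fd.ndof;
  std::fill(R.begin(), R.end(), 0.0);
  int kl = fd.bw, ku = fd.bw, ldab = 2 * kl + ku + 1;
  if (AB) {
    std::fill(AB->begin(), AB->end(), 0.0);
    std::fill(bcol->begin(), bcol->end(), 0.0);
    std::fill(crow->begin(), crow->end(), 0.0);
    *dcorner = 0.0;
  }
  double ur[4], uz[4], pp[4], uro[4], uzo[4], ppo[4];
  double res0[12], res1[12];
  double qbuf[4 * 64];

  for (int e = 0; e < fd.nel; ++e) {
    gather(fd, e, x, ur, uz, pp);
    gather(fd, e, x_old, uro, uzo, ppo);
    const double* qo = q_old + (size_t)e * 4 * fd.ndir;
    double* qn = q_new ? q_new + (size_t)e * 4 * fd.ndir : nullptr;
    elem_residual(fd, e, ur, uz, pp, uro, uzo, ppo, qo, dt, res0, qn);

    // local slot -> global dof id (platen mapped to n)
    int gid[12];
    for (int a = 0; a < 4; ++a) {
      int node = fd.conn[e + a * fd.nel];
      int du = fd.dof_ur[node], dz = fd.dof_uz[node], dp = fd.dof_p[node];
      gid[a] = du;
      gid[4 + a] = dz >= 0 ? dz : (dz == -2 ? n : -1);
      gid[8 + a] = dp;
    }
    for (int s = 0; s < 12; ++s)
      if (gid[s] >= 0) R[gid[s]] += res0[s];

    if (!AB) continue;

    // unique global dofs of this element
    int ug[12], nu_ = 0;
    for (int s = 0; s < 12; ++s) {
      if (gid[s] < 0) continue;
      bool seen = false;
      for (int t = 0; t < nu_; ++t) if (ug[t] == gid[s]) { seen = true; break; }
      if (!seen) ug[nu_++] = gid[s];
    }
    double urp[4], uzp[4], ppp[4];
    for (int t = 0; t < nu_; ++t) {
      int g = ug[t];
      bool is_p = false;
      for (int s = 8; s < 12; ++s) if (gid[s] == g) is_p = true;
      double base = (g < n) ? x[g] : x[n];
      double h = is_p ? (1e-3 + 1e-7 * std::fabs(base))
                      : (1e-10 + 1e-7 * std::fabs(base));
      for (int a = 0; a < 4; ++a) { urp[a] = ur[a]; uzp[a] = uz[a]; ppp[a] = pp[a]; }
      for (int s = 0; s < 12; ++s) {
        if (gid[s] != g) continue;
        if (s < 4) urp[s] += h;
        else if (s < 8) uzp[s - 4] += h;
        else ppp[s - 8] += h;
      }
      elem_residual(fd, e, urp, uzp, ppp, uro, uzo, ppo, qo, dt, res1,
                    qbuf);
      for (int s = 0; s < 12; ++s) {
        if (gid[s] < 0) continue;
        double v = (res1[s] - res0[s]) / h;
        if (v == 0.0) continue;
        int gi = gid[s];
        if (gi < n && g < n) {
          (*AB)[(size_t)g * ldab + (kl + ku + gi - g)] += v;
        } else if (gi == n && g < n) {
          (*crow)[g] += v;
        } else if (gi < n && g == n) {
          (*bcol)[gi] += v;
        } else {
          *dcorner += v;
        }
      }
    }
  }
  R[n] -= Fext;   // applied axial force on the platen (negative = compression)
}

}  // namespace

// [[Rcpp::export]]
List fe_newton_step(NumericVector x_in, NumericVector x_old,
                    NumericVector q_old, double dt, double Fext,
                    List fem, double tol_rel, double tol_abs_u,
                    int maxit) {
  FemData fd = unpack(fem);
  int n = fd.ndof;
  if (fd.ndir > 64) stop("too many fibril directions");
  std::vector<double> x(x_in.begin(), x_in.end());
  std::vector<double> xo(x_old.begin(), x_old.end());
  std::vector<double> R(n + 1), Rtry(n + 1);
  int kl = fd.bw, ku = fd.bw, ldab = 2 * kl + ku + 1;
  std::vector<double> AB((size_t)ldab * n), bcol(n), crow(n);
  std::vector<double> rhs(2 * (size_t)n);
  std::vector<int> ipiv(n);
  NumericVector q_new((size_t)fd.nel * 4 * fd.ndir);
  double dcorner = 0;

  double W0 = std::max(std::fabs(Fext), 1.0);
  double rn_u0 = -1, rn_p0 = -1;
  bool converged = false;
  int it = 0;
  double rn_u = 0, rn_p = 0;

  auto norms = [&](const std::vector<double>& RR, double& nu_, double& np_) {
    nu_ = std::fabs(RR[n]);
    np_ = 0;
    for (int nd = 0; nd < fd.nn; ++nd) {
      int du = fd.dof_ur[nd], dz = fd.dof_uz[nd], dp = fd.dof_p[nd];
      if (du >= 0) nu_ = std::max(nu_, std::fabs(RR[du]));
      if (dz >= 0) nu_ = std::max(nu_, std::fabs(RR[dz]));
      if (dp >= 0) np_ = std::max(np_, std::fabs(RR[dp]));
    }
  };

  rn_u0 = std::max(W0, 1e-300);   // momentum scale: the applied load
  rn_p0 = 1e-300;                 // continuity scale: running maximum
  // modified Newton: the banded Jacobian is factorised once and reused
  // until the residual reduction stalls, then refreshed
  std::vector<double> Rs(n + 1, 1.0), Cs(n + 1, 1.0), y2(n);
  double dsc = 0;
  bool have_jac = false;
  double rn_u_prev = -1;
  for (it = 0; it < maxit; ++it) {
    assemble(fd, x.data(), xo.data(), &q_old[0], dt, Fext,
             R, nullptr, nullptr, nullptr, nullptr, &q_new[0]);
    norms(R, rn_u, rn_p);
    if (rn_p > rn_p0) rn_p0 = rn_p;
    bool ok_u = rn_u < tol_rel * W0;
    bool ok_p = (rn_p < tol_rel * rn_p0) || (rn_p0 < 1e-250);
    if (ok_u && ok_p) { converged = true; break; }
    if (rn_u_prev > 0 && rn_u > 0.5 * rn_u_prev) have_jac = false;
    rn_u_prev = rn_u;
    if (!have_jac) {
      assemble(fd, x.data(), xo.data(), &q_old[0], dt, Fext,
               R, &AB, &bcol, &crow, &dcorner, &q_new[0]);
      norms(R, rn_u, rn_p);
      if (rn_p > rn_p0) rn_p0 = rn_p;

    // two-sided equilibration: the momentum and continuity blocks differ
    // by many orders of magnitude in SI units, which defeats partial
    // pivoting; scale rows then columns to O(1) before factorising.
    std::fill(Rs.begin(), Rs.end(), 0.0);
    std::fill(Cs.begin(), Cs.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      int ilo = std::max(0, j - ku), ihi = std::min(n - 1, j + kl);
      for (int i = ilo; i <= ihi; ++i) {
        double v = std::fabs(AB[(size_t)j * ldab + (kl + ku + i - j)]);
        if (v > Rs[i]) Rs[i] = v;
      }
      if (std::fabs(crow[j]) > Rs[n]) Rs[n] = std::fabs(crow[j]);
    }
    for (int i = 0; i < n; ++i)
      if (std::fabs(bcol[i]) > Rs[i]) Rs[i] = std::fabs(bcol[i]);
    if (std::fabs(dcorner) > Rs[n]) Rs[n] = std::fabs(dcorner);
    for (int i = 0; i <= n; ++i) Rs[i] = Rs[i] > 0 ? 1.0 / Rs[i] : 1.0;
    for (int j = 0; j < n; ++j) {
      int ilo = std::max(0, j - ku), ihi = std::min(n - 1, j + kl);
      for (int i = ilo; i <= ihi; ++i) {
        double v = std::fabs(AB[(size_t)j * ldab + (kl + ku + i - j)]) * Rs[i];
        if (v > Cs[j]) Cs[j] = v;
      }
      double v = std::fabs(crow[j]) * Rs[n];
      if (v > Cs[j]) Cs[j] = v;
    }
    for (int i = 0; i < n; ++i) {
      double v = std::fabs(bcol[i]) * Rs[i];
      if (v > Cs[n]) Cs[n] = v;
    }
    {
      double v = std::fabs(dcorner) * Rs[n];
      if (v > Cs[n]) Cs[n] = v;
    }
    for (int j = 0; j <= n; ++j) Cs[j] = Cs[j] > 0 ? 1.0 / Cs[j] : 1.0;
    for (int j = 0; j < n; ++j) {
      int ilo = std::max(0, j - ku), ihi = std::min(n - 1, j + kl);
      for (int i = ilo; i <= ihi; ++i)
        AB[(size_t)j * ldab + (kl + ku + i - j)] *= Rs[i] * Cs[j];
    }
      dsc = dcorner * Rs[n] * Cs[n];
      int info = 0;
      F77_CALL(dgbtrf)(&n, &n, &kl, &ku, AB.data(), &ldab, ipiv.data(),
                       &info);
      if (info != 0)
        return List::create(_["converged"] = false, _["iter"] = it,
                            _["reason"] = "singular_jacobian");
      // y2 = A^-1 (scaled border column)
      for (int i = 0; i < n; ++i) y2[i] = bcol[i] * Rs[i] * Cs[n];
      int one = 1;
      F77_CALL(dgbtrs)("N", &n, &kl, &ku, &one, AB.data(), &ldab,
                       ipiv.data(), y2.data(), &n, &info FCONE);
      if (info != 0)
        return List::create(_["converged"] = false, _["iter"] = it,
                            _["reason"] = "singular_jacobian");
      have_jac = true;
    }
    // bordered solve with the stored factorisation:
    // [A b; c' d] [dx; dl] = -[R_a; R_d] (in equilibrated variables)
    for (int i = 0; i < n; ++i) rhs[i] = -R[i] * Rs[i];
    {
      int info = 0, one = 1;
      F77_CALL(dgbtrs)("N", &n, &kl, &ku, &one, AB.data(), &ldab,
                       ipiv.data(), rhs.data(), &n, &info FCONE);
      if (info != 0)
        return List::create(_["converged"] = false, _["iter"] = it,
                            _["reason"] = "singular_jacobian");
    }
    double cx1 = 0, cx2 = 0;
    for (int j = 0; j < n; ++j) {
      double cs = crow[j] * Rs[n] * Cs[j];
      cx1 += cs * rhs[j];
      cx2 += cs * y2[j];
    }
    double denom = dsc - cx2;
    double num = -R[n] * Rs[n] - cx1;
    if (denom == 0.0)
      return List::create(_["converged"] = false, _["iter"] = it,
                          _["reason"] = "singular_border");
    double dl = num / denom;   // scaled platen increment
    // damped update: backtrack only on momentum-residual blow-up or
    // element inversion (poisoned residual); transient growth of the
    // continuity residual between iterations is normal.
    double alpha = 1.0;
    std::vector<double> xtry(n + 1);
    for (int ls = 0; ls < 5; ++ls) {
      for (int i = 0; i < n; ++i)
        xtry[i] = x[i] + alpha * Cs[i] * (rhs[i] - dl * y2[i]);
      xtry[n] = x[n] + alpha * Cs[n] * dl;
      assemble(fd, xtry.data(), xo.data(), &q_old[0], dt, Fext,
               Rtry, nullptr, nullptr, nullptr, nullptr, nullptr);
      double tu, tp;
      norms(Rtry, tu, tp);
      if ((tu <= std::max(10.0 * rn_u, tol_rel * W0) && tu < 1e29) ||
          ls == 4) {
        x = xtry;
        if (ls > 0) have_jac = false;
        break;
      }
      alpha *= 0.25;
    }
  }

  // final state-consistent residual (commit overstresses at converged x)
  assemble(fd, x.data(), xo.data(), &q_old[0], dt, Fext,
           R, nullptr, nullptr, nullptr, nullptr, &q_new[0]);
  double f_int_platen = R[n] + Fext;

  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["q"] = q_new,
                      _["converged"] = converged,
                      _["iter"] = it,
                      _["res_u"] = rn_u, _["res_p"] = rn_p,
                      _["f_int_platen"] = f_int_platen);
}

// [[Rcpp::export]]
List fe_residual(NumericVector x, NumericVector x_old, NumericVector q_old,
                 double dt, double Fext, List fem) {
  FemData fd = unpack(fem);
  std::vector<double> R(fd.ndof + 1);
  NumericVector q_new((size_t)fd.nel * 4 * fd.ndir);
  assemble(fd, &x[0], &x_old[0], &q_old[0], dt, Fext, R,
           nullptr, nullptr, nullptr, nullptr, &q_new[0]);
  return List::create(_["R"] = NumericVector(R.begin(), R.end()),
                      _["q"] = q_new);
}

// [[Rcpp::export]]
NumericVector fe_gauss_J(NumericVector x, List fem) {
  // volume ratio at each Gauss point (nel x 4), for diagnostics/permeability
  FemData fd = unpack(fem);
  NumericVector out((size_t)fd.nel * 4);
  double ur[4], uz[4], pp[4];
  for (int e = 0; e < fd.nel; ++e) {
    gather(fd, e, &x[0], ur, uz, pp);
    double Xr[4], Xz[4];
    for (int a = 0; a < 4; ++a) {
      int nn = fd.conn[e + a * fd.nel];
      Xr[a] = fd.Xr[nn]; Xz[a] = fd.Xz[nn];
    }
    for (int g = 0; g < 4; ++g) {
      double N[4], dNxi[4], dNeta[4];
      shape(gp_xi[g], gp_eta[g], N, dNxi, dNeta);
      double J00 = 0, J01 = 0, J10 = 0, J11 = 0, Rgp = 0;
      for (int a = 0; a < 4; ++a) {
        J00 += Xr[a] * dNxi[a]; J01 += Xr[a] * dNeta[a];
        J10 += Xz[a] * dNxi[a]; J11 += Xz[a] * dNeta[a];
        Rgp += N[a] * Xr[a];
      }
      double detref = J00 * J11 - J01 * J10;
      double dNdX[4][2];
      for (int a = 0; a < 4; ++a) {
        dNdX[a][0] = ( J11 * dNxi[a] - J10 * dNeta[a]) / detref;
        dNdX[a][1] = (-J01 * dNxi[a] + J00 * dNeta[a]) / detref;
      }
      double H00 = 0, H01 = 0, H10 = 0, H11 = 0, urg = 0;
      for (int a = 0; a < 4; ++a) {
        H00 += ur[a] * dNdX[a][0]; H01 += ur[a] * dNdX[a][1];
        H10 += uz[a] * dNdX[a][0]; H11 += uz[a] * dNdX[a][1];
        urg += N[a] * ur[a];
      }
      if (fd.mat.small_strain) {
        out[e * 4 + g] = 1 + H00 + H11 + urg / Rgp;
      } else {
        out[e * 4 + g] = ((1 + H00) * (1 + H11) - H01 * H10) *
          (1 + urg / Rgp);
      }
    }
  }
  return out;
}
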