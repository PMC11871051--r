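#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Adaptive velocity-Verlet integrator for an N-body point-charge Coulomb
// explosion, in Hartree atomic units throughout (bohr, m_e, hartree).
//
// The time step is tied to the instantaneous minimum pairwise distance,
//   dt = eta * sqrt(m_min * d_min^3 / max_ij(q_i q_j)),
// which resolves the stiff early repulsion and grows rapidly once the
// fragments separate, so the number of steps to a given residual-potential
// fraction is finite and small.  Pairwise force accumulation keeps the total
// momentum conserved to round-off by construction.
//
// Integration stops once the residual potential energy drops below
// pe_tol * E_total; the momenta at that point are reported as asymptotic.

static double pair_sweep(int n,
                         const std::vector<double> &x,
                         const std::vector<double> &y,
                         const std::vector<double> &z,
                         const std::vector<double> &q,
                         std::vector<double> &fx,
                         std::vector<double> &fy,
                         std::vector<double> &fz,
                         double &dmin) {
  double pe = 0.0;
  dmin = R_PosInf;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j];
      const double dy = y[i] - y[j];
      const double dz = z[i] - z[j];
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double r = std::sqrt(r2);
      if (r < dmin) dmin = r;
      const double qq = q[i] * q[j];
      pe += qq / r;
      const double f = qq / (r2 * r);
      fx[i] += f * dx; fx[j] -= f * dx;
      fy[i] += f * dy; fy[j] -= f * dy;
      fz[i] += f * dz; fz[j] -= f * dz;
    }
  }
  return pe;
}

// [[Rcpp::export]]
List ce_explode_cpp(NumericMatrix pos_bohr, NumericVector charges,
                    NumericVector mass_me, NumericMatrix v0,
                    double eta, double pe_tol, double max_steps) {
  const int n = pos_bohr.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  std::vector<double> fx(n), fy(n), fz(n), q(n), m(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos_bohr(i, 0); y[i] = pos_bohr(i, 1); z[i] = pos_bohr(i, 2);
    vx[i] = v0(i, 0); vy[i] = v0(i, 1); vz[i] = v0(i, 2);
    q[i] = charges[i]; m[i] = mass_me[i];
  }

  double qqmax = 0.0, mmin = R_PosInf;
  for (int i = 0; i < n; ++i) {
    if (m[i] < mmin) mmin = m[i];
    for (int j = i + 1; j < n; ++j) {
      const double qq = std::fabs(q[i] * q[j]);
      if (qq > qqmax) qqmax = qq;
    }
  }
  if (qqmax <= 0.0) stop("all pairwise charge products are zero; nothing to explode");

  double dmin;
  double pe = pair_sweep(n, x, y, z, q, fx, fy, fz, dmin);
  if (!R_FINITE(pe)) stop("coincident atom positions: potential energy is not finite");
  double ke0 = 0.0;
  for (int i = 0; i < n; ++i)
    ke0 += 0.5 * m[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
  const double pe0 = pe;
  const double etot = pe0 + ke0;
  if (etot <= 0.0) stop("total energy is not positive; fragments will not separate");

  double steps = 0.0;
  bool converged = true;
  while (pe > pe_tol * etot) {
    if (steps >= max_steps) { converged = false; break; }
    const double dt = eta * std::sqrt(mmin * dmin * dmin * dmin / qqmax);
    const double h = 0.5 * dt;
    for (int i = 0; i < n; ++i) {
      vx[i] += h * fx[i] / m[i];
      vy[i] += h * fy[i] / m[i];
      vz[i] += h * fz[i] / m[i];
      x[i] += dt * vx[i]; y[i] += dt * vy[i]; z[i] += dt * vz[i];
    }
    pe = pair_sweep(n, x, y, z, q, fx, fy, fz, dmin);
    for (int i = 0; i < n; ++i) {
      vx[i] += h * fx[i] / m[i];
      vy[i] += h * fy[i] / m[i];
      vz[i] += h * fz[i] / m[i];
    }
    steps += 1.0;
  }

  NumericMatrix p(n, 3), pos_final(n, 3);
  NumericVector ke(n);
  double ke_tot = 0.0;
  double Lx = 0.0, Ly = 0.0, Lz = 0.0, Lscale = 0.0;
  for (int i = 0; i < n; ++i) {
    p(i, 0) = m[i] * vx[i]; p(i, 1) = m[i] * vy[i]; p(i, 2) = m[i] * vz[i];
    pos_final(i, 0) = x[i]; pos_final(i, 1) = y[i]; pos_final(i, 2) = z[i];
    ke[i] = 0.5 * m[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    ke_tot += ke[i];
    const double lx = y[i] * p(i, 2) - z[i] * p(i, 1);
    const double ly = z[i] * p(i, 0) - x[i] * p(i, 2);
    const double lz = x[i] * p(i, 1) - y[i] * p(i, 0);
    Lx += lx; Ly += ly; Lz += lz;
    Lscale += std::sqrt(lx * lx + ly * ly + lz * lz);
  }
  NumericVector L = NumericVector::create(Lx, Ly, Lz);

  return List::create(
      _["p"] = p, _["pos_final_bohr"] = pos_final, _["ke_ha"] = ke,
      _["L_total"] = L, _["L_scale"] = Lscale,
      _["pe_initial_ha"] = pe0, _["ke_initial_ha"] = ke0,
      _["pe_residual_ha"] = pe, _["residual_fraction"] = pe / etot,
      _["ke_total_ha"] = ke_tot,
      _["energy_error"] = std::fabs(ke_tot + pe - etot) / etot,
      _["steps"] = steps, _["converged"] = converged);
}

// Brute-force pairwise Coulomb potential energy (hartree) of a configuration
// given in bohr; exposed for the energy bookkeeping on the R side.
// [[Rcpp::export]]
double ce_coulomb_energy_cpp(NumericMatrix pos_bohr, NumericVector charges) {
  const int n = pos_bohr.nrow();
  double pe = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = pos_bohr(i, 0) - pos_bohr(j, 0);
      const double dy = pos_bohr(i, 1) - pos_bohr(j, 1);
      const double dz = pos_bohr(i, 2) - pos_bohr(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r == 0.0)
        stop("atoms %d and %d are coincident (r = 0)", i + 1, j + 1);
      pe += charges[i] * charges[j] / r;
    }
  }
  return pe;
}
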