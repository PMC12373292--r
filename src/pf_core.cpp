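// Core explicit-Euler stepper for the coupled cell/lumen phase fields.
// Slice 0 of the state cube is the shared lumen field u_0; slices 1..M are
// cells. Dynamics: tau du/dt = D lap(u) + u(1-u)(u - 1/2 + f) with
//   f_i = alpha (Vt - V_i) - beta sum_{j != i, j in [0,M]} h(u_j)
//         + eta lap sum_{j != i, j in [1,M]} h(u_j) + gamma lap h(u_i)
//   f_0 = xi - beta sum_{j in [1,M]} h(u_j)
// h(u) = u^2 (3 - 2u). Boundaries are no-flux (mirror ghost cells).
// Loops are fused (laplacians evaluated on the fly) to keep the update
// memory-bandwidth friendly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double hfun(double u) { return u * u * (3.0 - 2.0 * u); }

// 5-point Neumann Laplacian (mirror ghosts) at (i, j), column-major n1 x n2
static inline double lap_at_2d(const double* u, int i, int j, int n1, int n2,
                               double inv_dx2) {
  const double c = u[i + (size_t)j * n1];
  const double xm = (i == 0) ? c : u[i - 1 + (size_t)j * n1];
  const double xp = (i == n1 - 1) ? c : u[i + 1 + (size_t)j * n1];
  const double ym = (j == 0) ? c : u[i + (size_t)(j - 1) * n1];
  const double yp = (j == n2 - 1) ? c : u[i + (size_t)(j + 1) * n1];
  return (xm + xp + ym + yp - 4.0 * c) * inv_dx2;
}

static inline double lap_at_3d(const double* u, int i, int j, int k,
                               int n1, int n2, int n3, double inv_dx2) {
  const size_t p = i + (size_t)j * n1 + (size_t)k * n1 * n2;
  const double c = u[p];
  const double xm = (i == 0) ? c : u[p - 1];
  const double xp = (i == n1 - 1) ? c : u[p + 1];
  const double ym = (j == 0) ? c : u[p - n1];
  const double yp = (j == n2 - 1) ? c : u[p + n1];
  const double zm = (k == 0) ? c : u[p - (size_t)n1 * n2];
  const double zp = (k == n3 - 1) ? c : u[p + (size_t)n1 * n2];
  return (xm + xp + ym + yp + zm + zp - 6.0 * c) * inv_dx2;
}

// [[Rcpp::export]]
List pf_step_block_2d(arma::cube U, int nsteps, double dx, double dt,
                      double D, double alpha, double beta, double gamma,
                      double eta, double xi, double tau, double Vtarget,
                      double clamp_lo, double clamp_hi) {
  const int n1 = U.n_rows, n2 = U.n_cols, nf = U.n_slices;
  const int M = nf - 1;
  const size_t npt = (size_t)n1 * n2;
  const double inv_dx2 = 1.0 / (dx * dx);
  const double cell_area = dx * dx;
  const double dt_tau = dt / tau;

  arma::cube H(n1, n2, nf), Unew(n1, n2, nf);
  arma::mat S_beta(n1, n2), lapScell(n1, n2);
  std::vector<double> vols(nf);
  bool ok = true;

  for (int s = 0; s < nsteps && ok; ++s) {
    // indicator fields and their volumes
    for (int m = 0; m < nf; ++m) {
      const double* u = U.slice_memptr(m);
      double* h = H.slice_memptr(m);
      double acc = 0.0;
      for (size_t p = 0; p < npt; ++p) { h[p] = hfun(u[p]); acc += h[p]; }
      vols[m] = acc * cell_area;
    }
    // S_beta = beta-sum seen by cells including the lumen; the lumen's own
    // exclusion sum is S_beta - H0 (cells only)
    {
      double* sb = S_beta.memptr();
      const double* h0 = H.slice_memptr(0);
      for (size_t p = 0; p < npt; ++p) sb[p] = h0[p];
      for (int m = 1; m < nf; ++m) {
        const double* h = H.slice_memptr(m);
        for (size_t p = 0; p < npt; ++p) sb[p] += h[p];
      }
    }
    if (M > 0) {
      // laplacian of the cells-only indicator sum
      const double* sb = S_beta.memptr();
      const double* h0 = H.slice_memptr(0);
      arma::mat Scell(n1, n2);
      double* sc = Scell.memptr();
      for (size_t p = 0; p < npt; ++p) sc[p] = sb[p] - h0[p];
      double* ls = lapScell.memptr();
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i)
          ls[i + (size_t)j * n1] = lap_at_2d(sc, i, j, n1, n2, inv_dx2);
    }

    // lumen update: f0 = xi - beta (S_beta - H0)
    {
      const double* u = U.slice_memptr(0);
      const double* h0 = H.slice_memptr(0);
      const double* sb = S_beta.memptr();
      double* un = Unew.slice_memptr(0);
      for (int j = 0; j < n2; ++j) {
        for (int i = 0; i < n1; ++i) {
          const size_t p = i + (size_t)j * n1;
          const double uu = u[p];
          const double f = xi - beta * (sb[p] - h0[p]);
          double v = uu + dt_tau * (D * lap_at_2d(u, i, j, n1, n2, inv_dx2) +
                                    uu * (1.0 - uu) * (uu - 0.5 + f));
          if (v < clamp_lo) v = clamp_lo;
          else if (v > clamp_hi) v = clamp_hi;
          un[p] = v;
        }
      }
    }
    // cell updates
    for (int m = 1; m < nf; ++m) {
      const double* u = U.slice_memptr(m);
      const double* h = H.slice_memptr(m);
      const double* sb = S_beta.memptr();
      const double* ls = lapScell.memptr();
      double* un = Unew.slice_memptr(m);
      const double avol = alpha * (Vtarget - vols[m]);
      const double ge = gamma - eta;
      for (int j = 0; j < n2; ++j) {
        for (int i = 0; i < n1; ++i) {
          const size_t p = i + (size_t)j * n1;
          const double uu = u[p];
          const double f = avol - beta * (sb[p] - h[p]) +
              ge * lap_at_2d(h, i, j, n1, n2, inv_dx2) + eta * ls[p];
          double v = uu + dt_tau * (D * lap_at_2d(u, i, j, n1, n2, inv_dx2) +
                                    uu * (1.0 - uu) * (uu - 0.5 + f));
          if (v < clamp_lo) v = clamp_lo;
          else if (v > clamp_hi) v = clamp_hi;
          un[p] = v;
        }
      }
    }
    U.swap(Unew);
    if (!U.is_finite()) ok = false;
  }
  return List::create(_["u"] = U, _["ok"] = ok);
}

// [[Rcpp::export]]
List pf_step_block_3d(List Ulist, int nsteps, double dx, double dt,
                      double D, double alpha, double beta, double gamma,
                      double eta, double xi, double tau, double Vtarget,
                      double clamp_lo, double clamp_hi) {
  const int nf = Ulist.size();
  const int M = nf - 1;
  std::vector<arma::cube> U(nf);
  for (int m = 0; m < nf; ++m) U[m] = as<arma::cube>(Ulist[m]);
  const int n1 = U[0].n_rows, n2 = U[0].n_cols, n3 = U[0].n_slices;
  const size_t npt = (size_t)n1 * n2 * n3;
  const double inv_dx2 = 1.0 / (dx * dx);
  const double cell_vol = dx * dx * dx;
  const double dt_tau = dt / tau;

  std::vector<arma::cube> H(nf), Unew(nf);
  for (int m = 0; m < nf; ++m) {
    H[m].set_size(n1, n2, n3);
    Unew[m].set_size(n1, n2, n3);
  }
  arma::cube S_beta(n1, n2, n3), lapScell(n1, n2, n3), Scell(n1, n2, n3);
  std::vector<double> vols(nf);
  bool ok = true;

  for (int s = 0; s < nsteps && ok; ++s) {
    for (int m = 0; m < nf; ++m) {
      const double* u = U[m].memptr();
      double* h = H[m].memptr();
      double acc = 0.0;
      for (size_t p = 0; p < npt; ++p) { h[p] = hfun(u[p]); acc += h[p]; }
      vols[m] = acc * cell_vol;
    }
    {
      double* sb = S_beta.memptr();
      const double* h0 = H[0].memptr();
      for (size_t p = 0; p < npt; ++p) sb[p] = h0[p];
      for (int m = 1; m < nf; ++m) {
        const double* h = H[m].memptr();
        for (size_t p = 0; p < npt; ++p) sb[p] += h[p];
      }
    }
    if (M > 0) {
      const double* sb = S_beta.memptr();
      const double* h0 = H[0].memptr();
      double* sc = Scell.memptr();
      for (size_t p = 0; p < npt; ++p) sc[p] = sb[p] - h0[p];
      double* ls = lapScell.memptr();
      for (int k = 0; k < n3; ++k)
        for (int j = 0; j < n2; ++j)
          for (int i = 0; i < n1; ++i)
            ls[i + (size_t)j * n1 + (size_t)k * n1 * n2] =
                lap_at_3d(sc, i, j, k, n1, n2, n3, inv_dx2);
    }
    for (int m = 0; m < nf; ++m) {
      const double* u = U[m].memptr();
      const double* h = H[m].memptr();
      const double* sb = S_beta.memptr();
      const double* ls = lapScell.memptr();
      double* un = Unew[m].memptr();
      const bool is_lumen = (m == 0);
      const double avol = alpha * (Vtarget - vols[m]);
      const double ge = gamma - eta;
      for (int k = 0; k < n3; ++k) {
        for (int j = 0; j < n2; ++j) {
          for (int i = 0; i < n1; ++i) {
            const size_t p = i + (size_t)j * n1 + (size_t)k * n1 * n2;
            const double uu = u[p];
            double f;
            if (is_lumen) {
              f = xi - beta * (sb[p] - h[p]);
            } else {
              f = avol - beta * (sb[p] - h[p]) +
                  ge * lap_at_3d(h, i, j, k, n1, n2, n3, inv_dx2) +
                  eta * ls[p];
            }
            double v = uu + dt_tau *
                (D * lap_at_3d(u, i, j, k, n1, n2, n3, inv_dx2) +
                 uu * (1.0 - uu) * (uu - 0.5 + f));
            if (v < clamp_lo) v = clamp_lo;
            else if (v > clamp_hi) v = clamp_hi;
            un[p] = v;
          }
        }
      }
    }
    for (int m = 0; m < nf; ++m) {
      U[m].swap(Unew[m]);
      if (!U[m].is_finite()) ok = false;
    }
  }
  List out(nf);
  for (int m = 0; m < nf; ++m) out[m] = U[m];
  return List::create(_["u"] = out, _["ok"] = ok);
}
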