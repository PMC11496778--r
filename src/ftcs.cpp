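#include <Rcpp.h>
using namespace Rcpp;

// Explicit FTCS integration of the axisymmetric diffusion equation
//   dC/dt = D ( d2C/dr2 + (1/r) dC/dr + d2C/dz2 )
// on a node-based grid r_i = i*dr (i = 0..Nr), z_j = j*dz (j = 0..Nz).
//
// Boundary conditions (fixed, matching the physical setup of a release at
// the bottom of a culture dish):
//   dC/dz = 0 at z = 0 (reflecting dish bottom; symmetric ghost node)
//   dC/dr = 0 at r = 0 (rotational symmetry axis; 1/r term replaced by its
//                       symmetric limit, so the radial Laplacian becomes
//                       4*(C[1]-C[0])/dr^2 on the axis)
//   C = 0 at z = z_max and r = r_max (open far field)
//
// The interior radial stencil D*[(C[i+1]-2C[i]+C[i-1])/dr^2 +
// (C[i+1]-C[i-1])/(2 r_i dr)] is algebraically identical to the
// finite-volume flux form with face radii r_{i +/- 1/2}, so the discrete
// mass (half-cell weights on the reflecting faces, disc of radius dr/2 on
// the axis) is conserved exactly up to the outflux through the open faces.
//
// [[Rcpp::export(name = ".ftcs_run")]]
List ftcs_run(NumericMatrix C0, double D, double dr, double dz, double dt,
              int n_steps, IntegerVector snap_steps, int bottom_every) {
  const int nr = C0.nrow();   // Nr + 1 nodes, index i <-> radius i*dr
  const int nz = C0.ncol();   // Nz + 1 nodes, index j <-> height j*dz
  std::vector<double> cur(C0.begin(), C0.end());
  std::vector<double> nxt(cur.size(), 0.0);

  const double ar = D * dt / (dr * dr);
  const double az = D * dt / (dz * dz);

  // precomputed radial neighbour weights: w_plus/w_minus for i >= 1
  std::vector<double> wp(nr), wm(nr);
  for (int i = 1; i < nr; ++i) {
    wp[i] = ar * (1.0 + 0.5 / (double)i);   // dr/(2 r_i) = 1/(2i)
    wm[i] = ar * (1.0 - 0.5 / (double)i);
  }

  List snaps;
  IntegerVector snap_at = clone(snap_steps);
  int next_snap = 0;

  int n_bottom = (bottom_every > 0) ? (n_steps / bottom_every + 1) : 0;
  NumericMatrix bottom(n_bottom, (bottom_every > 0) ? nr : 0);
  NumericVector bottom_t(n_bottom);
  int bot_row = 0;

  auto record = [&](int step) {
    while (next_snap < snap_at.size() && snap_at[next_snap] == step) {
      NumericMatrix s(nr, nz);
      std::copy(cur.begin(), cur.end(), s.begin());
      snaps.push_back(s);
      ++next_snap;
    }
    if (bottom_every > 0 && step % bottom_every == 0 && bot_row < n_bottom) {
      for (int i = 0; i < nr; ++i) bottom(bot_row, i) = cur[i]; // j = 0 column
      bottom_t[bot_row] = step * dt;
      ++bot_row;
    }
  };

  record(0);
  for (int step = 1; step <= n_steps; ++step) {
    for (int j = 0; j < nz - 1; ++j) {       // j = nz-1 held at 0 (Dirichlet)
      const int jm = (j == 0) ? 1 : j - 1;   // symmetric ghost at dish bottom
      const double *Cj = &cur[(size_t)j * nr];
      const double *Cjm = &cur[(size_t)jm * nr];
      const double *Cjp = &cur[(size_t)(j + 1) * nr];
      double *Nj = &nxt[(size_t)j * nr];

      // axis node i = 0
      Nj[0] = Cj[0] + 4.0 * ar * (Cj[1] - Cj[0]) +
              az * (Cjp[0] - 2.0 * Cj[0] + Cjm[0]);
      // interior radial nodes
      for (int i = 1; i < nr - 1; ++i) {
        Nj[i] = Cj[i] + wp[i] * (Cj[i + 1] - Cj[i]) -
                wm[i] * (Cj[i] - Cj[i - 1]) +
                az * (Cjp[i] - 2.0 * Cj[i] + Cjm[i]);
      }
      Nj[nr - 1] = 0.0;                      // r = r_max (Dirichlet)
    }
    for (int i = 0; i < nr; ++i) nxt[(size_t)(nz - 1) * nr + i] = 0.0;
    cur.swap(nxt);
    record(step);
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector bt(bot_row);
  NumericMatrix bm(bot_row, (bottom_every > 0) ? nr : 0);
  for (int k = 0; k < bot_row; ++k) {
    bt[k] = bottom_t[k];
    for (int i = 0; i < bm.ncol(); ++i) bm(k, i) = bottom(k, i);
  }
  return List::create(_["snapshots"] = snaps, _["bottom"] = bm,
                      _["bottom_times"] = bt);
}

// 3x3 median filter with edge replication; used as the default noise
// reduction on raw intensity frames before the ratio is formed.
// [[Rcpp::export(name = ".median3x3")]]
NumericMatrix median3x3(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  double v[9];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -1; di <= 1; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          v[k++] = x(ii, jj);
        }
      }
      std::nth_element(v, v + 4, v + 9);
      out(i, j) = v[4];
    }
  }
  return out;
}
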