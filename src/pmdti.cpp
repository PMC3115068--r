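// Numerical kernels: trilinear affine resampling, partial-volume joint
// histogram mutual information, voxelwise weighted tensor solves and 3x3
// symmetric eigen-decomposition. All voxel coordinates are 0-based to match
// the package's indexing convention (world = voxel index * voxel size).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Pull-back resampling: out(x) = in(A * [x, 1]) with trilinear interpolation
// and zeros outside the field of view. A is a 3x4 matrix in 0-based voxel
// coordinates.
// [[Rcpp::export]]
arma::cube cpp_affine_resample(const arma::cube& vol, const arma::mat& A) {
  const int nx = vol.n_rows, ny = vol.n_cols, nz = vol.n_slices;
  arma::cube out(nx, ny, nz, arma::fill::zeros);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      // precompute the j,k part of the affine product
      const double bx = A(0,1)*j + A(0,2)*k + A(0,3);
      const double by = A(1,1)*j + A(1,2)*k + A(1,3);
      const double bz = A(2,1)*j + A(2,2)*k + A(2,3);
      for (int i = 0; i < nx; ++i) {
        const double xs = A(0,0)*i + bx;
        const double ys = A(1,0)*i + by;
        const double zs = A(2,0)*i + bz;
        const int x0 = (int)std::floor(xs);
        const int y0 = (int)std::floor(ys);
        const int z0 = (int)std::floor(zs);
        if (x0 < -1 || x0 >= nx || y0 < -1 || y0 >= ny || z0 < -1 || z0 >= nz)
          continue;
        const double fx = xs - x0, fy = ys - y0, fz = zs - z0;
        double acc = 0.0;
        for (int dz = 0; dz <= 1; ++dz) {
          const int zk = z0 + dz;
          if (zk < 0 || zk >= nz) continue;
          const double wz = dz ? fz : 1.0 - fz;
          for (int dy = 0; dy <= 1; ++dy) {
            const int yj = y0 + dy;
            if (yj < 0 || yj >= ny) continue;
            const double wy = dy ? fy : 1.0 - fy;
            for (int dx = 0; dx <= 1; ++dx) {
              const int xi = x0 + dx;
              if (xi < 0 || xi >= nx) continue;
              const double wx = dx ? fx : 1.0 - fx;
              acc += wx * wy * wz * vol(xi, yj, zk);
            }
          }
        }
        out(i, j, k) = acc;
      }
    }
  }
  return out;
}

// Tricubic (Catmull-Rom) pull-back resampling; zeros outside the FOV.
// Sharper than trilinear: used for final reconstruction resamples where
// interpolation smoothing must be minimal.
// [[Rcpp::export]]
arma::cube cpp_affine_resample_cubic(const arma::cube& vol, const arma::mat& A) {
  const int nx = vol.n_rows, ny = vol.n_cols, nz = vol.n_slices;
  arma::cube out(nx, ny, nz, arma::fill::zeros);
  auto wcr = [](double t, double w[4]) {
    const double t2 = t * t, t3 = t2 * t;
    w[0] = 0.5 * (-t3 + 2 * t2 - t);
    w[1] = 0.5 * (3 * t3 - 5 * t2 + 2);
    w[2] = 0.5 * (-3 * t3 + 4 * t2 + t);
    w[3] = 0.5 * (t3 - t2);
  };
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const double bx = A(0,1)*j + A(0,2)*k + A(0,3);
      const double by = A(1,1)*j + A(1,2)*k + A(1,3);
      const double bz = A(2,1)*j + A(2,2)*k + A(2,3);
      for (int i = 0; i < nx; ++i) {
        const double xs = A(0,0)*i + bx;
        const double ys = A(1,0)*i + by;
        const double zs = A(2,0)*i + bz;
        const int x0 = (int)std::floor(xs);
        const int y0 = (int)std::floor(ys);
        const int z0 = (int)std::floor(zs);
        if (x0 < -1 || x0 >= nx || y0 < -1 || y0 >= ny || z0 < -1 || z0 >= nz)
          continue;
        double wx[4], wy[4], wz[4];
        wcr(xs - x0, wx); wcr(ys - y0, wy); wcr(zs - z0, wz);
        double acc = 0.0;
        for (int dz = -1; dz <= 2; ++dz) {
          const int zk = z0 + dz;
          if (zk < 0 || zk >= nz) continue;
          for (int dy = -1; dy <= 2; ++dy) {
            const int yj = y0 + dy;
            if (yj < 0 || yj >= ny) continue;
            const double wyz = wy[dy + 1] * wz[dz + 1];
            for (int dx = -1; dx <= 2; ++dx) {
              const int xi = x0 + dx;
              if (xi < 0 || xi >= nx) continue;
              acc += wx[dx + 1] * wyz * vol(xi, yj, zk);
            }
          }
        }
        out(i, j, k) = acc;
      }
    }
  }
  return out;
}

// Mutual information in nats from a joint histogram with bilinear
// partial-volume bin weighting, computed over voxels where either image is
// nonzero. Returns 0 for degenerate (constant) inputs.
// [[Rcpp::export]]
double cpp_mi_nats(const arma::vec& a, const arma::vec& b, const int bins) {
  const arma::uword n = a.n_elem;
  double amin = arma::datum::inf, amax = -arma::datum::inf;
  double bmin = arma::datum::inf, bmax = -arma::datum::inf;
  arma::uword nmask = 0;
  for (arma::uword t = 0; t < n; ++t) {
    if (a[t] != 0.0 || b[t] != 0.0) {
      ++nmask;
      if (a[t] < amin) amin = a[t];
      if (a[t] > amax) amax = a[t];
      if (b[t] < bmin) bmin = b[t];
      if (b[t] > bmax) bmax = b[t];
    }
  }
  if (nmask == 0 || amax <= amin || bmax <= bmin) return 0.0;
  const double ascale = (bins - 1) / (amax - amin);
  const double bscale = (bins - 1) / (bmax - bmin);
  arma::mat joint(bins, bins, arma::fill::zeros);
  for (arma::uword t = 0; t < n; ++t) {
    if (a[t] == 0.0 && b[t] == 0.0) continue;
    const double ca = (a[t] - amin) * ascale;
    const double cb = (b[t] - bmin) * bscale;
    int ia = (int)std::floor(ca), ib = (int)std::floor(cb);
    if (ia >= bins - 1) ia = bins - 2;
    if (ib >= bins - 1) ib = bins - 2;
    const double fa = ca - ia, fb = cb - ib;
    joint(ia,     ib)     += (1 - fa) * (1 - fb);
    joint(ia + 1, ib)     += fa * (1 - fb);
    joint(ia,     ib + 1) += (1 - fa) * fb;
    joint(ia + 1, ib + 1) += fa * fb;
  }
  joint /= (double)nmask;
  const arma::vec pa = arma::sum(joint, 1);
  const arma::rowvec pb = arma::sum(joint, 0);
  double ha = 0.0, hb = 0.0, hab = 0.0;
  for (int i = 0; i < bins; ++i) {
    if (pa[i] > 0) ha -= pa[i] * std::log(pa[i]);
    if (pb[i] > 0) hb -= pb[i] * std::log(pb[i]);
  }
  for (int i = 0; i < bins; ++i)
    for (int j = 0; j < bins; ++j)
      if (joint(i, j) > 0) hab -= joint(i, j) * std::log(joint(i, j));
  return ha + hb - hab;
}

// Marginal entropy (nats) of one image with the same masking and PV binning
// conventions as cpp_mi_nats, so that MI(A, A) == H(A) holds exactly.
// [[Rcpp::export]]
double cpp_entropy_nats(const arma::vec& a, const int bins) {
  return cpp_mi_nats(a, a, bins);
}

// Per-voxel weighted least squares solve of the log-linearized tensor model.
// X: nvol x p design; Y: nvol x nvox log-signals; W: nvol x nvox weights.
// Returns p x nvox coefficients.
// [[Rcpp::export]]
arma::mat cpp_wls_fit(const arma::mat& X, const arma::mat& Y, const arma::mat& W) {
  const arma::uword p = X.n_cols, nvox = Y.n_cols;
  arma::mat coef(p, nvox, arma::fill::zeros);
  arma::mat Xw(X.n_rows, p);
  for (arma::uword v = 0; v < nvox; ++v) {
    const arma::vec w = W.col(v);
    Xw = X.each_col() % w;
    const arma::mat Axx = X.t() * Xw;
    const arma::vec rhs = X.t() * (w % Y.col(v));
    arma::vec sol;
    if (arma::solve(sol, Axx, rhs, arma::solve_opts::no_approx))
      coef.col(v) = sol;
    else
      coef.col(v).fill(arma::datum::nan);
  }
  return coef;
}

// Eigen-decomposition of voxelwise symmetric tensors.
// D: 6 x nvox, rows (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
// Returns eigenvalues (3 x nvox, descending) and the principal eigenvector
// (3 x nvox).
// [[Rcpp::export]]
List cpp_eig3(const arma::mat& D) {
  const arma::uword nvox = D.n_cols;
  arma::mat evals(3, nvox), pdd(3, nvox);
  arma::mat33 T;
  arma::vec eigval;
  arma::mat eigvec;
  for (arma::uword v = 0; v < nvox; ++v) {
    T(0,0) = D(0,v); T(1,1) = D(1,v); T(2,2) = D(2,v);
    T(0,1) = T(1,0) = D(3,v);
    T(0,2) = T(2,0) = D(4,v);
    T(1,2) = T(2,1) = D(5,v);
    arma::eig_sym(eigval, eigvec, T);  // ascending
    evals(0,v) = eigval[2]; evals(1,v) = eigval[1]; evals(2,v) = eigval[0];
    pdd.col(v) = eigvec.col(2);
  }
  return List::create(Named("values") = evals, Named("vectors") = pdd);
}
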