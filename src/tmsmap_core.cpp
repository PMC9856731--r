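// Numerical kernels: thin-wire Biot-Savart accumulation over coil segments
// and a Jacobi-preconditioned conjugate gradient for the singular (pure
// Neumann) scalar-potential system.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// dA/dt at field points from straight current segments (midpoint rule).
// points: n x 3 (m); mids: m x 3 segment midpoints (m); dl: m x 3 signed
// segment vectors (m, direction = current sense). didt in A/s.
// Returns list(field = n x 3 in V/m, min_dist = per-point minimum exact
// distance to any wire segment, m).
// [[Rcpp::export]]
List bs_dadt_cpp(const arma::mat& points, const arma::mat& mids,
                 const arma::mat& dl, double didt) {
  const arma::uword n = points.n_rows, m = mids.n_rows;
  arma::mat out(n, 3, arma::fill::zeros);
  arma::vec mind(n);
  mind.fill(arma::datum::inf);
  const double pref = 1e-7 * didt; // mu0/(4*pi) * dI/dt
  arma::vec dl2(m);
  for (arma::uword j = 0; j < m; ++j)
    dl2(j) = dl(j, 0) * dl(j, 0) + dl(j, 1) * dl(j, 1) + dl(j, 2) * dl(j, 2);
  for (arma::uword i = 0; i < n; ++i) {
    const double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    double ax = 0.0, ay = 0.0, az = 0.0, dmin = arma::datum::inf;
    for (arma::uword j = 0; j < m; ++j) {
      const double rx = px - mids(j, 0);
      const double ry = py - mids(j, 1);
      const double rz = pz - mids(j, 2);
      const double d2 = rx * rx + ry * ry + rz * rz;
      // exact distance to the segment: project onto dl, clamp to ends
      double t = (rx * dl(j, 0) + ry * dl(j, 1) + rz * dl(j, 2)) / dl2(j);
      if (t > 0.5) t = 0.5;
      if (t < -0.5) t = -0.5;
      const double sx = rx - t * dl(j, 0);
      const double sy = ry - t * dl(j, 1);
      const double sz = rz - t * dl(j, 2);
      const double ds2 = sx * sx + sy * sy + sz * sz;
      if (ds2 < dmin) dmin = ds2;
      const double inv = 1.0 / std::sqrt(d2);
      ax += dl(j, 0) * inv;
      ay += dl(j, 1) * inv;
      az += dl(j, 2) * inv;
    }
    out(i, 0) = pref * ax;
    out(i, 1) = pref * ay;
    out(i, 2) = pref * az;
    mind(i) = std::sqrt(dmin);
  }
  return List::create(_["field"] = out, _["min_dist"] = mind);
}

// Jacobi-preconditioned CG for symmetric positive semi-definite A with the
// constant vector in its null space and compatible b. Iterates are kept in
// the mean-zero gauge by construction when x0 = 0 and b is compatible; the
// caller re-centers the solution anyway.
// [[Rcpp::export]]
List cg_jacobi_cpp(const arma::sp_mat& A, const arma::vec& b, double tol,
                   int max_iter) {
  const arma::uword n = b.n_elem;
  arma::vec x(n, arma::fill::zeros);
  arma::vec d = arma::vec(A.diag());
  // guard: zero diagonals cannot occur for conducting nodes, but be safe
  d.transform([](double v) { return v > 0.0 ? 1.0 / v : 0.0; });
  arma::vec r = b;
  arma::vec z = d % r;
  arma::vec p = z;
  double rz = arma::dot(r, z);
  const double bnorm = arma::norm(b);
  if (bnorm == 0.0) {
    return List::create(_["x"] = x, _["relres"] = 0.0, _["iterations"] = 0,
                        _["history"] = NumericVector::create(0.0));
  }
  std::vector<double> hist;
  double relres = arma::norm(r) / bnorm;
  hist.push_back(relres);
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    arma::vec Ap = A * p;
    double pAp = arma::dot(p, Ap);
    if (pAp <= 0.0) break; // numerical breakdown along null space
    double alpha = rz / pAp;
    x += alpha * p;
    r -= alpha * Ap;
    relres = arma::norm(r) / bnorm;
    hist.push_back(relres);
    if (relres <= tol) break;
    z = d % r;
    double rz_new = arma::dot(r, z);
    p = z + (rz_new / rz) * p;
    rz = rz_new;
  }
  return List::create(_["x"] = x, _["relres"] = relres,
                      _["iterations"] = it,
                      _["history"] = NumericVector(hist.begin(), hist.end()));
}

// Trilinear interpolation of per-voxel vector data at arbitrary continuous
// voxel-center coordinates. vals: nv x k matrix indexed by flat voxel id
// (0-based, x fastest); dims: grid dimensions; q: m x 3 query coordinates in
// voxel-center units (0 = center of first voxel). mask: 1 where the voxel
// value is valid. Queries touching an invalid corner get NaN.
// [[Rcpp::export]]
arma::mat trilinear_cpp(const arma::mat& vals, const arma::ivec& dims,
                        const arma::vec& mask, const arma::mat& q) {
  const arma::uword m = q.n_rows, k = vals.n_cols;
  const int nx = dims(0), ny = dims(1), nz = dims(2);
  arma::mat out(m, k, arma::fill::zeros);
  for (arma::uword i = 0; i < m; ++i) {
    double xf = q(i, 0), yf = q(i, 1), zf = q(i, 2);
    int x0 = (int)std::floor(xf), y0 = (int)std::floor(yf),
        z0 = (int)std::floor(zf);
    double tx = xf - x0, ty = yf - y0, tz = zf - z0;
    bool bad = false;
    arma::rowvec res(k, arma::fill::zeros);
    for (int c = 0; c < 8 && !bad; ++c) {
      int xi = x0 + (c & 1), yi = y0 + ((c >> 1) & 1), zi = z0 + ((c >> 2) & 1);
      if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz) {
        bad = true;
        break;
      }
      arma::uword id = (arma::uword)xi + nx * ((arma::uword)yi + (arma::uword)ny * zi);
      if (mask(id) == 0.0) {
        bad = true;
        break;
      }
      double w = (((c & 1) ? tx : 1 - tx) * (((c >> 1) & 1) ? ty : 1 - ty) *
                  (((c >> 2) & 1) ? tz : 1 - tz));
      res += w * vals.row(id);
    }
    if (bad)
      out.row(i).fill(arma::datum::nan);
    else
      out.row(i) = res;
  }
  return out;
}
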