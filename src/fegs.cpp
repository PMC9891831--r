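#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Leading eigenvalue of the symmetric nonnegative matrix held in `m`
// (row-major, n x n), by power iteration with a small diagonal shift
// (10% of the max row sum).  For a nonnegative symmetric matrix the Perron
// eigenvalue dominates in magnitude; the shift breaks the exact +/- tie of
// bipartite-like cases without flattening the spectral gap the way a full
// row-sum shift would.
static double leading_eigenvalue(const std::vector<double>& m, int n,
                                 double tol, int maxit) {
  double shift = 0.0;
  for (int i = 0; i < n; ++i) {
    double rs = 0.0;
    for (int j = 0; j < n; ++j) rs += m[(size_t)i * n + j];
    if (rs > shift) shift = rs;
  }
  shift *= 0.1;
  std::vector<double> v(n, 1.0 / std::sqrt((double)n)), w(n);
  double lam = 0.0, lam_old = R_PosInf;
  for (int it = 0; it < maxit; ++it) {
    for (int i = 0; i < n; ++i) {
      double acc = shift * v[i];
      const double* row = &m[(size_t)i * n];
      for (int j = 0; j < n; ++j) acc += row[j] * v[j];
      w[i] = acc;
    }
    double nrm = 0.0, ray = 0.0;
    for (int i = 0; i < n; ++i) { nrm += w[i] * w[i]; ray += w[i] * v[i]; }
    nrm = std::sqrt(nrm);
    if (nrm == 0.0) return 0.0;  // zero matrix and zero shift
    lam = ray;                   // Rayleigh quotient of A (v is unit)
    for (int i = 0; i < n; ++i) v[i] = w[i] / nrm;
    if (std::fabs(lam - lam_old) <= tol * std::max(1.0, std::fabs(lam)))
      break;
    lam_old = lam;
  }
  return lam - shift;
}

// Per-property leading-eigenvalue FEGS features.
//
// codes: sequence as 1-based indices into the alphabetical amino-acid
//        alphabet (length N >= 2).
// ranks: 20 x P integer matrix; ranks[a-1, p] is the rank (1..20) of amino
//        acid a under property p.
// For each property the 3D curve is accumulated (vertex step for the first
// residue, pair steps phi(a) + phi(b)/4 afterwards), the Euclidean /
// path-length quotient matrix over curve points P_1..P_N is formed, and
// lambda_1 / N is returned.
// [[Rcpp::export]]
NumericVector cpp_fegs_lambdas(IntegerVector codes, IntegerMatrix ranks,
                               double tol, int maxit) {
  const int n = codes.size();
  const int P = ranks.ncol();
  if (n < 2) stop("sequence must have at least 2 residues");
  if (ranks.nrow() != 20) stop("ranks must be a 20 x P matrix");
  NumericVector out(P);
  std::vector<double> cx(20), cy(20);
  std::vector<double> px(n), py(n), pz(n), pref(n);
  std::vector<double> m((size_t)n * n);
  for (int p = 0; p < P; ++p) {
    for (int a = 0; a < 20; ++a) {
      int r = ranks(a, p);
      if (r < 1 || r > 20) stop("ranks must lie in 1..20");
      double ang = 2.0 * M_PI * r / 20.0;
      cx[a] = std::cos(ang);
      cy[a] = std::sin(ang);
    }
    // curve points P_1..P_N (origin P_0 excluded)
    int s0 = codes[0] - 1;
    px[0] = cx[s0]; py[0] = cy[s0]; pz[0] = 1.0;
    for (int i = 1; i < n; ++i) {
      int a = codes[i - 1] - 1, b = codes[i] - 1;
      px[i] = px[i - 1] + cx[a] + 0.25 * cx[b];
      py[i] = py[i - 1] + cy[a] + 0.25 * cy[b];
      pz[i] = pz[i - 1] + 1.25;
    }
    // prefix sums of edge lengths along the curve
    pref[0] = 0.0;
    for (int i = 1; i < n; ++i) {
      double dx = px[i] - px[i - 1], dy = py[i] - py[i - 1],
             dz = pz[i] - pz[i - 1];
      pref[i] = pref[i - 1] + std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    for (int i = 0; i < n; ++i) {
      m[(size_t)i * n + i] = 0.0;
      for (int j = i + 1; j < n; ++j) {
        double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
        double q = std::sqrt(dx * dx + dy * dy + dz * dz) /
                   (pref[j] - pref[i]);
        m[(size_t)i * n + j] = q;
        m[(size_t)j * n + i] = q;
      }
    }
    out[p] = leading_eigenvalue(m, n, tol, maxit) / n;
  }
  return out;
}

// Leading eigenvalue of a symmetric nonnegative R matrix (exposed for the
// dual-route eigenvalue tests).
// [[Rcpp::export]]
double cpp_leading_eigenvalue(NumericMatrix mat, double tol, int maxit) {
  int n = mat.nrow();
  if (mat.ncol() != n) stop("matrix must be square");
  std::vector<double> m((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) m[(size_t)i * n + j] = mat(i, j);
  return leading_eigenvalue(m, n, tol, maxit);
}
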