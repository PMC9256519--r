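#include <Rcpp.h>
using namespace Rcpp;

// One pass of an IIR filter (direct form II transposed), zero initial state.
// Templated on the state size so the delay line lives in registers for the
// common Butterworth band-pass orders.
template <int NZ>
static void df2t_fixed(const double* b, const double* a,
                       const double* x, double* y, int n) {
  double z[NZ];
  for (int k = 0; k < NZ; ++k) z[k] = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int k = 0; k < NZ - 1; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    z[NZ - 1] = b[NZ] * xi - a[NZ] * yi;
    y[i] = yi;
  }
}

static void df2t_any(const double* b, const double* a, int nz,
                     const double* x, double* y, int n) {
  std::vector<double> z(nz, 0.0);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int k = 0; k < nz - 1; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    z[nz - 1] = b[nz] * xi - a[nz] * yi;
    y[i] = yi;
  }
}

static void df2t(const double* b, const double* a, int nz,
                 const double* x, double* y, int n) {
  switch (nz) {
  case 2: df2t_fixed<2>(b, a, x, y, n); break;
  case 4: df2t_fixed<4>(b, a, x, y, n); break;
  case 6: df2t_fixed<6>(b, a, x, y, n); break;
  case 8: df2t_fixed<8>(b, a, x, y, n); break;
  case 12: df2t_fixed<12>(b, a, x, y, n); break;
  case 16: df2t_fixed<16>(b, a, x, y, n); break;
  default: df2t_any(b, a, nz, x, y, n);
  }
}

// Zero-phase (forward-backward) IIR filtering of the rows of x, with odd
// (point-symmetric) reflection padding of npad samples at both ends to keep
// edge transients out of the record. Coefficients normalized so a[0] = 1.
// [[Rcpp::export]]
NumericMatrix filtfilt_rows_cpp(NumericVector b, NumericVector a,
                                NumericMatrix x, int npad) {
  const int nr = x.nrow(), n = x.ncol();
  if (npad > n - 1) npad = n - 1;
  const int nz = (int)std::max(b.size(), a.size()) - 1;
  std::vector<double> bv(nz + 1, 0.0), av(nz + 1, 0.0);
  for (int k = 0; k < (int)b.size(); ++k) bv[k] = b[k] / a[0];
  for (int k = 1; k < (int)a.size(); ++k) av[k] = a[k] / a[0];
  av[0] = 1.0;

  const int m = n + 2 * npad;
  std::vector<double> row(n), xe(m), ye(m);
  NumericMatrix out(nr, n);
  for (int r = 0; r < nr; ++r) {
    for (int i = 0; i < n; ++i) row[i] = x(r, i);
    for (int i = 0; i < npad; ++i) xe[i] = 2.0 * row[0] - row[npad - i];
    std::copy(row.begin(), row.end(), xe.begin() + npad);
    for (int i = 0; i < npad; ++i)
      xe[npad + n + i] = 2.0 * row[n - 1] - row[n - 2 - i];
    df2t(bv.data(), av.data(), nz, xe.data(), ye.data(), m);
    std::reverse(ye.begin(), ye.end());
    df2t(bv.data(), av.data(), nz, ye.data(), xe.data(), m);
    std::reverse(xe.begin(), xe.end());
    for (int i = 0; i < n; ++i) out(r, i) = xe[npad + i];
  }
  return out;
}
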