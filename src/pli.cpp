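#include <Rcpp.h>
using namespace Rcpp;

// PLI for all region pairs of one epoch: phases is an n_regions x n_samples
// matrix of instantaneous phase. PLI_ij = | mean_t sign(sin(phi_i - phi_j)) |
// with sign(0) = 0. sin(phi_i - phi_j) is expanded through precomputed
// sin/cos rows (stored contiguously per region so the pair scan is
// cache-friendly); each pair costs two multiplies and a compare per sample.
// [[Rcpp::export]]
NumericMatrix pli_matrix_cpp(NumericMatrix phases) {
  const int n = phases.nrow(), ns = phases.ncol();
  std::vector<double> s((size_t)n * ns), c((size_t)n * ns);
  for (int r = 0; r < n; ++r) {
    double* sr = &s[(size_t)r * ns];
    double* cr = &c[(size_t)r * ns];
    for (int t = 0; t < ns; ++t) {
      const double p = phases(r, t);
      sr[t] = std::sin(p);
      cr[t] = std::cos(p);
    }
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n - 1; ++i) {
    const double* si = &s[(size_t)i * ns];
    const double* ci = &c[(size_t)i * ns];
    for (int j = i + 1; j < n; ++j) {
      const double* sj = &s[(size_t)j * ns];
      const double* cj = &c[(size_t)j * ns];
      double acc = 0.0;
      for (int t = 0; t < ns; ++t) {
        const double v = si[t] * cj[t] - ci[t] * sj[t];
        acc += (v > 0.0) - (v < 0.0);
      }
      const double pli = std::fabs(acc / ns);
      out(i, j) = pli;
      out(j, i) = pli;
    }
  }
  return out;
}
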