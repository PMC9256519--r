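#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of lag-coupled phase oscillators:
//   dtheta_i = [omega_i + sum_j K_ij sin(theta_j - theta_i + tau_ij)] dt
//              + sigma sqrt(dt) dW_i
// Each undirected edge (i, j, K, tau) pulls the pair toward the locked state
// theta_i - theta_j = tau (region i leads region j by tau radians).
// Uses R's RNG so results are governed by set.seed() on the R side.
// [[Rcpp::export]]
NumericMatrix sim_phase_oscillators_cpp(int n_regions, int n_steps, double dt,
                                        NumericVector omega,
                                        IntegerVector edge_i,
                                        IntegerVector edge_j,
                                        NumericVector k,
                                        NumericVector tau,
                                        double freq_noise_sd,
                                        NumericVector theta0) {
  const int n_edges = edge_i.size();
  NumericMatrix theta(n_regions, n_steps);
  std::vector<double> cur(n_regions), drift(n_regions);
  for (int r = 0; r < n_regions; ++r) cur[r] = theta0[r];
  const double sqdt = std::sqrt(dt);

  for (int t = 0; t < n_steps; ++t) {
    for (int r = 0; r < n_regions; ++r) theta(r, t) = cur[r];
    for (int r = 0; r < n_regions; ++r) drift[r] = omega[r];
    for (int e = 0; e < n_edges; ++e) {
      const int a = edge_i[e], b = edge_j[e];
      // symmetric coupling with a common equilibrium theta_a - theta_b = tau
      const double s = std::sin(cur[b] - cur[a] + tau[e]);
      drift[a] += k[e] * s;
      drift[b] -= k[e] * s;
    }
    if (freq_noise_sd > 0.0) {
      for (int r = 0; r < n_regions; ++r)
        cur[r] += drift[r] * dt + freq_noise_sd * sqdt * R::norm_rand();
    } else {
      for (int r = 0; r < n_regions; ++r)
        cur[r] += drift[r] * dt;
    }
  }
  return theta;
}
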