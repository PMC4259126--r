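#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Euler-Maruyama integration of the coupled bistable-oscillator network
//
//   dZ_i = [ (a|Z_i|^4 + b|Z_i|^2 + c + i*omega_i) Z_i + sum_j G_ij Z_j ] dt
//          + sigma sqrt(dt) (eta1 + i eta2)
//
// G is the *pre-scaled* coupling matrix (the caller applies the global
// scale factor).  Noise draws come from R's RNG so that set.seed() on the
// R side makes the trajectory fully reproducible.  The two Gaussian draws
// per node per step are consumed in a fixed order (real then imaginary,
// node-major), which tests rely on when matching coupled and uncoupled
// runs seed-for-seed.
//
// [[Rcpp::export]]
ComplexMatrix em_simulate_cpp(NumericMatrix G, double a, double b, double c,
                              NumericVector omega, double sigma, double dt,
                              int nsteps, ComplexVector z0, double guard) {
  const int N = G.nrow();
  if (G.ncol() != N) stop("coupling matrix must be square");
  if (omega.size() != N || z0.size() != N)
    stop("omega and z0 must have one entry per node");
  if (nsteps < 1) stop("nsteps must be >= 1");

  // sparse directed edge list: coupling input to i accumulates w * Z_j
  std::vector<int> e_to, e_from;
  std::vector<double> e_w;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (G(i, j) != 0.0) {
        e_to.push_back(i);
        e_from.push_back(j);
        e_w.push_back(G(i, j));
      }
  const size_t n_edges = e_w.size();

  ComplexMatrix out(N, nsteps + 1);
  Rcomplex *optr = out.begin();
  std::vector<std::complex<double> > z(N), znew(N), coup(N);
  for (int i = 0; i < N; ++i) {
    z[i] = std::complex<double>(z0[i].r, z0[i].i);
    optr[i].r = z[i].real();
    optr[i].i = z[i].imag();
  }

  const double sq = sigma * std::sqrt(dt);
  const bool noisy = sigma > 0.0;
  const double guard2 = guard * guard;

  for (int k = 0; k < nsteps; ++k) {
    std::fill(coup.begin(), coup.end(), std::complex<double>(0.0, 0.0));
    for (size_t e = 0; e < n_edges; ++e)
      coup[e_to[e]] += e_w[e] * z[e_from[e]];
    for (int i = 0; i < N; ++i) {
      const double u = std::norm(z[i]);  // |Z|^2
      const std::complex<double> lin(a * u * u + b * u + c, omega[i]);
      std::complex<double> step = z[i] + dt * (lin * z[i] + coup[i]);
      if (noisy)
        step += std::complex<double>(sq * norm_rand(), sq * norm_rand());
      znew[i] = step;
    }
    Rcomplex *col = optr + (size_t)(k + 1) * N;
    for (int i = 0; i < N; ++i) {
      if (!(std::norm(znew[i]) <= guard2))
        stop("trajectory diverged (|Z| > %f) at step %d, node %d", guard,
             k + 1, i + 1);
      z[i] = znew[i];
      col[i].r = z[i].real();
      col[i].i = z[i].imag();
    }
  }
  return out;
}
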