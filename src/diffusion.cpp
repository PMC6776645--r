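#include <Rcpp.h>
using namespace Rcpp;

// Explicit FTCS step for dc/dt = D * laplacian(c) on a square grid with
// reflecting (zero-flux) boundaries, which conserves total mass exactly.
// Stability requires dt <= dx^2 / (4 D); the R wrapper enforces the guard.
// [[Rcpp::export(name = ".diffuse_steps_cpp")]]
NumericMatrix diffuse_steps_cpp(NumericMatrix c0, double D, double dx,
                                double dt, int nsteps) {
  const int nr = c0.nrow(), nc = c0.ncol();
  NumericMatrix a = clone(c0);
  NumericMatrix b(nr, nc);
  const double alpha = D * dt / (dx * dx);
  for (int s = 0; s < nsteps; ++s) {
    for (int j = 0; j < nc; ++j) {
      const int jl = (j == 0) ? 0 : j - 1;
      const int jr = (j == nc - 1) ? nc - 1 : j + 1;
      for (int i = 0; i < nr; ++i) {
        const int iu = (i == 0) ? 0 : i - 1;
        const int id = (i == nr - 1) ? nr - 1 : i + 1;
        b(i, j) = a(i, j) + alpha * (a(iu, j) + a(id, j) + a(i, jl) +
                                     a(i, jr) - 4.0 * a(i, j));
      }
    }
    std::swap(a, b);
  }
  return a;
}
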