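// Hines-ordered Gaussian elimination for symmetric tree systems.
// Solves A x = b where A has diagonal `diag`, and for every non-root
// compartment i an off-diagonal coupling -off[i] to parent[i] (0-based,
// parent[i] < i, parent of the root = -1).  This is the backward-Euler
// system matrix for both the cable equation and particle diffusion.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".hines_solve")]]
NumericVector hines_solve(IntegerVector parent, NumericVector diag,
                          NumericVector off, NumericVector rhs) {
  int n = diag.size();
  if (parent.size() != n || off.size() != n || rhs.size() != n)
    stop("mismatched system sizes");
  std::vector<double> d(diag.begin(), diag.end());
  std::vector<double> b(rhs.begin(), rhs.end());
  // elimination from the leaves towards the root
  for (int i = n - 1; i >= 1; --i) {
    int p = parent[i];
    if (p < 0 || p >= i) stop("parents must be topologically ordered");
    if (d[i] == 0.0) stop("singular system: zero pivot");
    double f = off[i] / d[i];
    d[p] -= f * off[i];
    b[p] += f * b[i];
  }
  if (d[0] == 0.0) stop("singular system: zero pivot at root");
  NumericVector x(n);
  x[0] = b[0] / d[0];
  for (int i = 1; i < n; ++i) x[i] = (b[i] + off[i] * x[parent[i]]) / d[i];
  return x;
}
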