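#include <Rcpp.h>
using namespace Rcpp;

// Reservoir state recursion x(n) = tanh(W_in u(n) + W_nn x(n-1)), x(0) = x0.
// Returns the NN x T state matrix for an input epoch u (C x T).
// [[Rcpp::export(name = ".reservoir_states")]]
NumericMatrix reservoir_states(NumericMatrix W_in, NumericMatrix W_nn,
                               NumericMatrix u, NumericVector x0) {
  const int NN = W_in.nrow();
  const int C = W_in.ncol();
  const int T = u.ncol();
  if (u.nrow() != C) stop("input channel count does not match W_in");
  if (W_nn.nrow() != NN || W_nn.ncol() != NN)
    stop("W_nn must be NN x NN");
  if (x0.size() != NN) stop("x0 must have length NN");

  NumericMatrix states(NN, T);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> nx(NN);

  for (int n = 0; n < T; ++n) {
    for (int i = 0; i < NN; ++i) {
      double s = 0.0;
      for (int c = 0; c < C; ++c) s += W_in(i, c) * u(c, n);
      nx[i] = s;
    }
    for (int i = 0; i < NN; ++i) {
      double s = nx[i];
      for (int j = 0; j < NN; ++j) s += W_nn(i, j) * x[j];
      states(i, n) = std::tanh(s);
    }
    for (int i = 0; i < NN; ++i) x[i] = states(i, n);
  }
  return states;
}
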