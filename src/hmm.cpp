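#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Scaled forward-backward over concatenated independent sequences.
// logB: frames x K emission log-densities; lengths: frames per sequence.
// Each sequence restarts from the initial distribution pi.
// Returns gamma (frames x K), xi (K x K summed expected transition counts,
// never crossing sequence boundaries), and the total log-likelihood.
// [[Rcpp::export]]
List fb_cpp(const arma::mat& logB, const arma::vec& pi, const arma::mat& A,
            const arma::ivec& lengths) {
  const int K = logB.n_cols;
  const int n = logB.n_rows;
  arma::mat gamma(n, K, arma::fill::zeros);
  arma::mat xi(K, K, arma::fill::zeros);
  double loglik = 0.0;

  int off = 0;
  for (arma::uword s = 0; s < lengths.n_elem; ++s) {
    const int T = lengths(s);
    // shift emission logs per frame for numerical stability
    arma::mat B(T, K);
    arma::vec shift(T);
    for (int t = 0; t < T; ++t) {
      double m = logB.row(off + t).max();
      shift(t) = m;
      for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(off + t, k) - m);
    }
    arma::mat alpha(T, K), beta(T, K);
    arma::vec c(T);
    // forward
    arma::rowvec a = pi.t() % B.row(0);
    c(0) = arma::accu(a);
    alpha.row(0) = a / c(0);
    for (int t = 1; t < T; ++t) {
      a = (alpha.row(t - 1) * A) % B.row(t);
      c(t) = arma::accu(a);
      alpha.row(t) = a / c(t);
    }
    // backward
    beta.row(T - 1).ones();
    for (int t = T - 2; t >= 0; --t) {
      arma::rowvec b = (beta.row(t + 1) % B.row(t + 1)) * A.t();
      beta.row(t) = b / c(t + 1);
    }
    // posteriors
    for (int t = 0; t < T; ++t) {
      arma::rowvec g = alpha.row(t) % beta.row(t);
      gamma.row(off + t) = g / arma::accu(g);
    }
    // expected transition counts
    for (int t = 0; t < T - 1; ++t) {
      arma::mat x = (alpha.row(t).t() * (beta.row(t + 1) % B.row(t + 1))) % A;
      xi += x / (c(t + 1));
    }
    loglik += arma::accu(arma::log(c)) + arma::accu(shift);
    off += T;
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = loglik);
}

// Viterbi decoding per sequence; returns 1-based state path.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(const arma::mat& logB, const arma::vec& logpi,
                          const arma::mat& logA, const arma::ivec& lengths) {
  const int K = logB.n_cols;
  const int n = logB.n_rows;
  IntegerVector path(n);
  int off = 0;
  for (arma::uword s = 0; s < lengths.n_elem; ++s) {
    const int T = lengths(s);
    arma::mat delta(T, K);
    arma::imat psi(T, K);
    delta.row(0) = logpi.t() + logB.row(off);
    for (int t = 1; t < T; ++t) {
      for (int k = 0; k < K; ++k) {
        double best = -arma::datum::inf;
        int arg = 0;
        for (int j = 0; j < K; ++j) {
          double v = delta(t - 1, j) + logA(j, k);
          if (v > best) { best = v; arg = j; }
        }
        delta(t, k) = best + logB(off + t, k);
        psi(t, k) = arg;
      }
    }
    int k = delta.row(T - 1).index_max();
    path[off + T - 1] = k + 1;
    for (int t = T - 2; t >= 0; --t) {
      k = psi(t + 1, k);
      path[off + t] = k + 1;
    }
    off += T;
  }
  return path;
}
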