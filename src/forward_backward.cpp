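// Scaled forward-backward recursions for a (possibly sub-stochastic)
// hidden Markov chain, run independently over per-subject segments of a
// concatenated sequence.  Sub-stochastic inputs arise in variational
// inference where exp(E[log A]) need not have unit row sums; the log
// normalizer returned here is then the variational log-evidence term.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// logB: T x K matrix of (expected) log emission densities
// logA: K x K matrix of (expected) log transition probabilities
// logpi: length-K (expected) log initial distribution
// starts, ends: 1-based inclusive row spans, one per subject
// Returns gamma (T x K posteriors), xi (K x K pooled expected transition
// counts), first_gamma (K, summed over subjects' first timepoints) and
// logZ (sum of per-subject log normalizers).
// [[Rcpp::export(name = ".fb_cpp")]]
Rcpp::List forward_backward_cpp(const arma::mat& logB,
                                const arma::mat& logA,
                                const arma::vec& logpi,
                                const arma::ivec& starts,
                                const arma::ivec& ends) {
  const uword T = logB.n_rows, K = logB.n_cols, S = starts.n_elem;
  mat gamma(T, K, fill::zeros);
  mat xi(K, K, fill::zeros);
  vec first_gamma(K, fill::zeros);
  double logZ = 0.0;

  const mat A = exp(logA);
  const vec pi0 = exp(logpi);

  for (uword s = 0; s < S; ++s) {
    const uword t0 = (uword)(starts(s) - 1), t1 = (uword)(ends(s) - 1);
    const uword n = t1 - t0 + 1;

    // emission likelihoods rescaled per row for stability
    mat B(n, K);
    vec off(n);
    for (uword t = 0; t < n; ++t) {
      double m = logB.row(t0 + t).max();
      off(t) = m;
      B.row(t) = exp(logB.row(t0 + t) - m);
    }

    mat alpha(n, K);
    vec c(n);
    rowvec a = pi0.t() % B.row(0);
    c(0) = accu(a);
    alpha.row(0) = a / c(0);
    for (uword t = 1; t < n; ++t) {
      a = (alpha.row(t - 1) * A) % B.row(t);
      c(t) = accu(a);
      if (!(c(t) > 0)) Rcpp::stop("forward recursion underflow");
      alpha.row(t) = a / c(t);
    }
    logZ += accu(log(c)) + accu(off);

    mat beta(n, K);
    beta.row(n - 1).ones();
    for (uword t = n - 1; t-- > 0;) {
      rowvec bb = beta.row(t + 1) % B.row(t + 1);
      beta.row(t) = (A * bb.t()).t() / c(t + 1);
      // xi_t(i,j) = alpha_t(i) A(i,j) B_{t+1}(j) beta_{t+1}(j) / c_{t+1}
      xi += (alpha.row(t).t() * (bb / c(t + 1))) % A;
    }

    mat g = alpha % beta;
    g.each_col() /= sum(g, 1);  // guard tiny drift
    gamma.rows(t0, t1) = g;
    first_gamma += g.row(0).t();
  }

  return Rcpp::List::create(Rcpp::Named("gamma") = gamma,
                            Rcpp::Named("xi") = xi,
                            Rcpp::Named("first_gamma") = first_gamma,
                            Rcpp::Named("logZ") = logZ);
}
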