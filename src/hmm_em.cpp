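// Baum-Welch EM for a multi-trial Gaussian-observation HMM.
// Subjects enter as independent trials sharing {pi0, P, mu, sigma};
// the forward-backward recursion restarts at every trial boundary.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// log N(x | mu_k, sigma_k) for every row of X and every state k
static arma::mat gaussianLogDensity(const arma::mat& X,
                                    const arma::mat& mu,
                                    const arma::cube& sigma) {
  const arma::uword T = X.n_rows, d = X.n_cols, K = mu.n_rows;
  arma::mat logB(T, K);
  const double c = -0.5 * (double)d * std::log(2.0 * M_PI);
  for (arma::uword k = 0; k < K; ++k) {
    arma::mat L;
    if (!arma::chol(L, sigma.slice(k), "lower"))
      stop("covariance of state %d is not positive definite", (int)k + 1);
    const double logdet = 2.0 * arma::accu(arma::log(L.diag()));
    arma::mat centred = X.each_row() - mu.row(k);
    // solve L z = x for each row: z = L^{-1} (x - mu); quad form = ||z||^2
    arma::mat Z = arma::solve(arma::trimatl(L), centred.t());
    arma::rowvec q = arma::sum(Z % Z, 0);
    logB.col(k) = (c - 0.5 * logdet - 0.5 * q).t();
  }
  return logB;
}

// Scaled forward-backward for one trial.
// Fills gamma (TxK) and xi (KxK summed over t); returns log-likelihood.
static double forwardBackward(const arma::mat& logB,
                              const arma::mat& P,
                              const arma::rowvec& pi0,
                              arma::mat& gamma,
                              arma::mat& xiSum) {
  const arma::uword T = logB.n_rows, K = logB.n_cols;
  arma::vec rowMax = arma::max(logB, 1);
  arma::mat B = arma::exp(logB.each_col() - rowMax);

  arma::mat alpha(T, K), beta(T, K);
  arma::vec scale(T);
  double loglik = 0.0;

  alpha.row(0) = pi0 % B.row(0);
  scale(0) = arma::accu(alpha.row(0));
  if (scale(0) <= 0) stop("zero forward probability at t = 1");
  alpha.row(0) /= scale(0);
  for (arma::uword t = 1; t < T; ++t) {
    alpha.row(t) = (alpha.row(t - 1) * P) % B.row(t);
    scale(t) = arma::accu(alpha.row(t));
    if (scale(t) <= 0) stop("zero forward probability at t = %d", (int)t + 1);
    alpha.row(t) /= scale(t);
  }
  loglik = arma::accu(arma::log(scale)) + arma::accu(rowMax);

  beta.row(T - 1).ones();
  for (arma::uword t = T - 1; t-- > 0;) {
    beta.row(t) = (beta.row(t + 1) % B.row(t + 1)) * P.t();
    beta.row(t) /= scale(t + 1);
  }

  gamma = alpha % beta;
  gamma.each_col() /= arma::sum(gamma, 1);

  xiSum.zeros(K, K);
  for (arma::uword t = 0; t + 1 < T; ++t) {
    arma::mat xi = (alpha.row(t).t() * (beta.row(t + 1) % B.row(t + 1))) % P;
    xi /= scale(t + 1);
    xiSum += xi;
  }
  return loglik;
}

// [[Rcpp::export(name = ".cppPosterior")]]
List cppPosterior(const arma::mat& X, const arma::mat& P,
                  const arma::rowvec& pi0, const arma::mat& mu,
                  const arma::cube& sigma) {
  arma::mat logB = gaussianLogDensity(X, mu, sigma);
  arma::mat gamma, xiSum;
  double ll = forwardBackward(logB, P, pi0, gamma, xiSum);
  return List::create(_["gamma"] = gamma, _["loglik"] = ll);
}

// [[Rcpp::export(name = ".cppBaumWelch")]]
List cppBaumWelch(const List& trials, const arma::mat& P0,
                  const arma::rowvec& pi0In, const arma::mat& mu0,
                  const arma::cube& sigma0, int maxIter, double tol,
                  double ridgeScale) {
  const int nTrials = trials.size();
  const arma::uword K = mu0.n_rows, d = mu0.n_cols;

  arma::mat P = P0, mu = mu0;
  arma::rowvec pi0 = pi0In;
  arma::cube sigma = sigma0;
  std::vector<arma::mat> Xs(nTrials);
  for (int i = 0; i < nTrials; ++i) Xs[i] = as<arma::mat>(trials[i]);

  std::vector<double> llTrace;
  List gammaOut(nTrials);
  bool degenerate = false;
  double llOld = -arma::datum::inf;

  for (int iter = 0; iter < maxIter; ++iter) {
    double ll = 0.0;
    arma::mat xiTot(K, K, arma::fill::zeros);
    arma::rowvec piAcc(K, arma::fill::zeros);
    arma::rowvec gammaSum(K, arma::fill::zeros);
    arma::mat muAcc(K, d, arma::fill::zeros);
    arma::cube S(d, d, K, arma::fill::zeros);

    for (int i = 0; i < nTrials; ++i) {
      arma::mat logB = gaussianLogDensity(Xs[i], mu, sigma);
      arma::mat gamma, xiSum;
      ll += forwardBackward(logB, P, pi0, gamma, xiSum);
      xiTot += xiSum;
      piAcc += gamma.row(0);
      gammaSum += arma::sum(gamma, 0);
      muAcc += gamma.t() * Xs[i];
      // weighted raw scatter; recentred around the new mean in the M-step
      for (arma::uword k = 0; k < K; ++k)
        S.slice(k) += (Xs[i].each_col() % gamma.col(k)).t() * Xs[i];
      gammaOut[i] = gamma;
    }
    llTrace.push_back(ll);

    // M-step
    pi0 = piAcc / arma::accu(piAcc);
    for (arma::uword k = 0; k < K; ++k) {
      double rowSum = arma::accu(xiTot.row(k));
      if (rowSum > 0) P.row(k) = xiTot.row(k) / rowSum;
    }
    for (arma::uword k = 0; k < K; ++k) {
      if (gammaSum(k) < 1e-8) { degenerate = true; continue; }
      arma::rowvec m = muAcc.row(k) / gammaSum(k);
      arma::mat cov = S.slice(k) / gammaSum(k) - m.t() * m;
      cov = 0.5 * (cov + cov.t());
      double ridge = ridgeScale * arma::trace(cov) / (double)d;
      if (!(ridge > 0)) ridge = ridgeScale;
      cov.diag() += ridge;
      mu.row(k) = m;
      sigma.slice(k) = cov;
    }

    if (iter > 0 && std::abs(ll - llOld) < tol * (1.0 + std::abs(llOld)))
      break;
    llOld = ll;
  }

  // final E-step pass so posteriors match returned parameters
  double llFinal = 0.0;
  for (int i = 0; i < nTrials; ++i) {
    arma::mat logB = gaussianLogDensity(Xs[i], mu, sigma);
    arma::mat gamma, xiSum;
    llFinal += forwardBackward(logB, P, pi0, gamma, xiSum);
    gammaOut[i] = gamma;
  }
  llTrace.push_back(llFinal);

  return List::create(
      _["P"] = P, _["pi0"] = pi0, _["mu"] = mu, _["sigma"] = sigma,
      _["loglik"] = llFinal, _["loglikTrace"] = llTrace,
      _["gamma"] = gammaOut, _["degenerate"] = degenerate);
}
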