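#include <Rcpp.h>
using namespace Rcpp;

// Forward (and forward-backward) recursions over the three-state fluorophore
// chain: 0 = emitting, 1 = not emitting, 2 = bleached. Initial distribution
// (1/2, 1/2, 0); transitions
//   emitting -> emitting  alpha
//   emitting -> dark      1 - alpha
//   dark     -> emitting  beta
//   dark     -> dark      1 - beta - p_bleach
//   dark     -> bleached  p_bleach
//   bleached -> bleached  1
// Dark and bleached states share the same emission density (no light), so
// the caller passes two per-frame log emission densities: log_e (emitting)
// and log_d (dark/bleached). Scaling per frame keeps the recursion stable.

// [[Rcpp::export]]
double forward_logmarg_cpp(NumericVector log_e, NumericVector log_d,
                           double alpha, double beta, double p_bleach) {
  const int K = log_e.size();
  double logZ = 0.0;
  double m = std::max(log_e[0], log_d[0]);
  double aE = 0.5 * std::exp(log_e[0] - m);
  double aD = 0.5 * std::exp(log_d[0] - m);
  double aB = 0.0;
  double s = aE + aD + aB;
  logZ += m + std::log(s);
  aE /= s; aD /= s; aB /= s;
  for (int k = 1; k < K; ++k) {
    const double pE = alpha * aE + beta * aD;
    const double pD = (1.0 - alpha) * aE + (1.0 - beta - p_bleach) * aD;
    const double pB = p_bleach * aD + aB;
    m = std::max(log_e[k], log_d[k]);
    const double eE = std::exp(log_e[k] - m);
    const double eD = std::exp(log_d[k] - m);
    aE = pE * eE;
    aD = pD * eD;
    aB = pB * eD;
    s = aE + aD + aB;
    logZ += m + std::log(s);
    aE /= s; aD /= s; aB /= s;
  }
  return logZ;
}

// Forward-backward: returns the log marginal likelihood and the posterior
// probability of the emitting state in every frame.
// [[Rcpp::export]]
List forward_backward_cpp(NumericVector log_e, NumericVector log_d,
                          double alpha, double beta, double p_bleach) {
  const int K = log_e.size();
  NumericVector fE(K), fD(K), fB(K), mv(K), sv(K);
  double logZ = 0.0;
  double m = std::max(log_e[0], log_d[0]);
  double aE = 0.5 * std::exp(log_e[0] - m);
  double aD = 0.5 * std::exp(log_d[0] - m);
  double aB = 0.0;
  double s = aE + aD + aB;
  logZ += m + std::log(s);
  aE /= s; aD /= s; aB /= s;
  fE[0] = aE; fD[0] = aD; fB[0] = aB; mv[0] = m; sv[0] = s;
  for (int k = 1; k < K; ++k) {
    const double pE = alpha * aE + beta * aD;
    const double pD = (1.0 - alpha) * aE + (1.0 - beta - p_bleach) * aD;
    const double pB = p_bleach * aD + aB;
    m = std::max(log_e[k], log_d[k]);
    const double eE = std::exp(log_e[k] - m);
    const double eD = std::exp(log_d[k] - m);
    aE = pE * eE;
    aD = pD * eD;
    aB = pB * eD;
    s = aE + aD + aB;
    logZ += m + std::log(s);
    aE /= s; aD /= s; aB /= s;
    fE[k] = aE; fD[k] = aD; fB[k] = aB; mv[k] = m; sv[k] = s;
  }
  NumericVector q(K);
  double bE = 1.0, bD = 1.0, bB = 1.0;
  q[K - 1] = fE[K - 1];  // scaled alphas already sum to 1
  for (int k = K - 2; k >= 0; --k) {
    const double eE = std::exp(log_e[k + 1] - mv[k + 1]);
    const double eD = std::exp(log_d[k + 1] - mv[k + 1]);
    const double nE = (alpha * eE * bE + (1.0 - alpha) * eD * bD) / sv[k + 1];
    const double nD = (beta * eE * bE +
                       (1.0 - beta - p_bleach) * eD * bD +
                       p_bleach * eD * bB) / sv[k + 1];
    const double nB = eD * bB / sv[k + 1];
    bE = nE; bD = nD; bB = nB;
    const double tot = fE[k] * bE + fD[k] * bD + fB[k] * bB;
    q[k] = fE[k] * bE / tot;
  }
  return List::create(Named("log_marginal") = logZ,
                      Named("q_emitting") = q);
}
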