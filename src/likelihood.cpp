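// Likelihood kernels: two-state trait pruning + MCMC, and 61-state codon pruning.
// Trees arrive as postorder edge arrays (children precede parents), node ids
// 1-based with tips 1..n_tip and the root at n_tip+1 (ape convention).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 2x2 transition probabilities for the binary chain with gain a (0->1) and
// loss b (1->0): closed form via e^{-(a+b)t}.
static inline void pmat2(double a, double b, double t, double P[2][2]) {
  double s = a + b;
  double e = std::exp(-s * t);
  P[0][0] = (b + a * e) / s;
  P[0][1] = (a - a * e) / s;
  P[1][0] = (b - b * e) / s;
  P[1][1] = (a + b * e) / s;
}

// Core pruning over the 2-state chain. class_gain/class_loss give the rate
// pair for each branch class; constraint[node-1] in {-1,0,1} fossilizes a node.
static double trait_loglik_core(const IntegerVector& eparent,
                                const IntegerVector& echild,
                                const NumericVector& elen,
                                const IntegerVector& eclass,
                                const std::vector<double>& class_gain,
                                const std::vector<double>& class_loss,
                                const NumericMatrix& tip_partials,
                                const IntegerVector& constraint,
                                const double root_prior[2],
                                int n_tip, int n_node, int root) {
  std::vector<double> part(2 * n_node);
  for (int v = 0; v < n_node; ++v) {
    if (v < n_tip) {
      part[2 * v] = tip_partials(v, 0);
      part[2 * v + 1] = tip_partials(v, 1);
    } else {
      part[2 * v] = part[2 * v + 1] = 1.0;
    }
  }
  double logscale = 0.0;
  int ne = eparent.size();
  for (int i = 0; i < ne; ++i) {
    int child = echild[i] - 1, parent = eparent[i] - 1, cls = eclass[i] - 1;
    double c0 = part[2 * child], c1 = part[2 * child + 1];
    int con = constraint[child];
    if (con == 0) c1 = 0.0; else if (con == 1) c0 = 0.0;
    double m = std::max(c0, c1);
    if (!(m > 0.0)) return R_NegInf;
    c0 /= m; c1 /= m;
    logscale += std::log(m);
    double P[2][2];
    pmat2(class_gain[cls], class_loss[cls], elen[i], P);
    part[2 * parent]     *= P[0][0] * c0 + P[0][1] * c1;
    part[2 * parent + 1] *= P[1][0] * c0 + P[1][1] * c1;
  }
  double r0 = part[2 * (root - 1)], r1 = part[2 * (root - 1) + 1];
  int rcon = constraint[root - 1];
  if (rcon == 0) r1 = 0.0; else if (rcon == 1) r0 = 0.0;
  double lik = root_prior[0] * r0 + root_prior[1] * r1;
  if (!(lik > 0.0)) return R_NegInf;
  return std::log(lik) + logscale;
}

// [[Rcpp::export]]
double trait_loglik_cpp(IntegerVector eparent, IntegerVector echild,
                        NumericVector elen, IntegerVector eclass,
                        NumericMatrix class_rates, NumericMatrix tip_partials,
                        IntegerVector constraint, NumericVector root_prior,
                        int n_tip, int n_node, int root) {
  int n_class = class_rates.nrow();
  std::vector<double> cg(n_class), cl(n_class);
  for (int k = 0; k < n_class; ++k) {
    cg[k] = class_rates(k, 0);
    cl[k] = class_rates(k, 1);
  }
  double rp[2] = { root_prior[0], root_prior[1] };
  return trait_loglik_core(eparent, echild, elen, eclass, cg, cl,
                           tip_partials, constraint, rp, n_tip, n_node, root);
}

// Metropolis-Hastings over log-rates at likelihood power `beta` (stepping-stone
// stones use beta < 1; beta = 0 samples the prior). One parameter updated per
// iteration, cycling. Exponential(prior_mean) priors on the natural scale.
// Proposal sds adapt toward 0.44 acceptance during burn-in only. Uses R's RNG,
// so set.seed() in R controls the chain.
// [[Rcpp::export]]
List trait_mcmc_cpp(IntegerVector eparent, IntegerVector echild,
                    NumericVector elen, IntegerVector eclass,
                    IntegerVector class_gain_idx, IntegerVector class_loss_idx,
                    NumericMatrix tip_partials, IntegerVector constraint,
                    int root_prior_type, int root_class,
                    NumericVector theta0, double prior_mean, double beta,
                    int n_iter, int n_burn, int thin, NumericVector prop_sd0,
                    int n_tip, int n_node, int root) {
  int npar = theta0.size();
  int n_class = class_gain_idx.size();
  std::vector<double> ltheta(npar);
  for (int j = 0; j < npar; ++j) ltheta[j] = std::log(theta0[j]);
  std::vector<double> sd(npar);
  for (int j = 0; j < npar; ++j) sd[j] = prop_sd0[j];

  std::vector<double> cg(n_class), cl(n_class);
  auto loglik_at = [&](const std::vector<double>& lt) {
    for (int k = 0; k < n_class; ++k) {
      cg[k] = std::exp(lt[class_gain_idx[k] - 1]);
      cl[k] = std::exp(lt[class_loss_idx[k] - 1]);
    }
    // 1 = stationary, 2 = uniform, 3 = fixed absent, 4 = fixed present
    double rp[2];
    if (root_prior_type == 2) { rp[0] = rp[1] = 0.5; }
    else if (root_prior_type == 3) { rp[0] = 1.0; rp[1] = 0.0; }
    else if (root_prior_type == 4) { rp[0] = 0.0; rp[1] = 1.0; }
    else {
      double a = cg[root_class - 1], b = cl[root_class - 1];
      rp[0] = b / (a + b); rp[1] = a / (a + b);
    }
    return trait_loglik_core(eparent, echild, elen, eclass, cg, cl,
                             tip_partials, constraint, rp, n_tip, n_node, root);
  };
  // log prior + log Jacobian for sampling on the log scale
  auto logprior_at = [&](const std::vector<double>& lt) {
    double lp = 0.0;
    for (int j = 0; j < npar; ++j) lp += -std::exp(lt[j]) / prior_mean + lt[j];
    return lp;
  };

  double cur_ll = loglik_at(ltheta);
  double cur_lp = logprior_at(ltheta);
  int n_samp = (n_iter - n_burn) / thin;
  NumericMatrix samples(n_samp, npar);
  NumericVector samp_ll(n_samp);
  int isamp = 0;
  std::vector<int> acc(npar, 0), tries(npar, 0);
  std::vector<int> acc_win(npar, 0), tries_win(npar, 0);
  long n_acc_total = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    int j = (iter - 1) % npar;
    double old = ltheta[j];
    ltheta[j] = old + R::rnorm(0.0, sd[j]);
    double new_ll = loglik_at(ltheta);
    double new_lp = logprior_at(ltheta);
    double logr = beta * (new_ll - cur_ll) + (new_lp - cur_lp);
    bool take = std::isfinite(new_ll) &&
      (logr >= 0.0 || std::log(R::runif(0.0, 1.0)) < logr);
    if (take) {
      cur_ll = new_ll; cur_lp = new_lp;
      ++acc[j]; ++acc_win[j]; ++n_acc_total;
    } else {
      ltheta[j] = old;
    }
    ++tries[j]; ++tries_win[j];
    if (iter <= n_burn && tries_win[j] >= 50) {
      double r = (double)acc_win[j] / tries_win[j];
      sd[j] *= std::exp(r - 0.44);
      if (sd[j] < 1e-3) sd[j] = 1e-3;
      if (sd[j] > 20.0) sd[j] = 20.0;
      acc_win[j] = 0; tries_win[j] = 0;
    }
    if (iter > n_burn && (iter - n_burn) % thin == 0 && isamp < n_samp) {
      for (int k = 0; k < npar; ++k) samples(isamp, k) = std::exp(ltheta[k]);
      samp_ll[isamp] = cur_ll;
      ++isamp;
    }
  }
  NumericVector theta_end(npar), sd_end(npar);
  for (int j = 0; j < npar; ++j) {
    theta_end[j] = std::exp(ltheta[j]);
    sd_end[j] = sd[j];
  }
  return List::create(_["samples"] = samples, _["loglik"] = samp_ll,
                      _["acceptance"] = (double)n_acc_total / n_iter,
                      _["theta_end"] = theta_end, _["prop_sd"] = sd_end);
}

// Eigen machinery for a reversible generator Q with stationary pi:
// B = D Q D^{-1} is symmetric for D = diag(sqrt(pi)); P(t) acts on partials as
// A1 * (exp(lam t) .* (A2 * x)) with A1 = D^{-1} V, A2 = V' D.
struct RevEig {
  arma::mat A1, A2;
  arma::vec lam;
};

static RevEig rev_eig(const arma::mat& Q, const arma::vec& pi) {
  arma::vec d = arma::sqrt(pi);
  arma::mat B = arma::diagmat(d) * Q * arma::diagmat(1.0 / d);
  B = 0.5 * (B + B.t());
  RevEig e;
  arma::mat V;
  arma::eig_sym(e.lam, V, B);
  e.A1 = arma::diagmat(1.0 / d) * V;
  e.A2 = V.t() * arma::diagmat(d);
  return e;
}

// Pruning over n_state codon states for all sites at once (BLAS-heavy).
// eclass indexes into Qlist; tip_states are 0-based, -1 = fully ambiguous.
// [[Rcpp::export]]
NumericVector codon_loglik_cpp(IntegerVector eparent, IntegerVector echild,
                               NumericVector elen, IntegerVector eclass,
                               List Qlist, NumericVector pi,
                               IntegerMatrix tip_states,
                               NumericVector root_prior,
                               int n_tip, int n_node, int root) {
  int ns = pi.size();
  int n_site = tip_states.ncol();
  arma::vec piv(pi.begin(), ns);
  std::vector<RevEig> eigs;
  for (int k = 0; k < Qlist.size(); ++k) {
    arma::mat Q = as<arma::mat>(Qlist[k]);
    eigs.push_back(rev_eig(Q, piv));
  }
  std::vector<arma::mat> part(n_node);
  for (int v = 0; v < n_node; ++v) {
    if (v < n_tip) {
      arma::mat M(ns, n_site, arma::fill::zeros);
      for (int s = 0; s < n_site; ++s) {
        int st = tip_states(v, s);
        if (st < 0) M.col(s).ones(); else M(st, s) = 1.0;
      }
      part[v] = M;
    } else {
      part[v] = arma::mat(ns, n_site, arma::fill::ones);
    }
  }
  arma::rowvec logscale(n_site, arma::fill::zeros);
  int ne = eparent.size();
  for (int i = 0; i < ne; ++i) {
    int child = echild[i] - 1, parent = eparent[i] - 1, cls = eclass[i] - 1;
    arma::mat& C = part[child];
    arma::rowvec m = arma::max(C, 0);
    for (int s = 0; s < n_site; ++s) {
      if (m[s] > 0.0) { C.col(s) /= m[s]; logscale[s] += std::log(m[s]); }
      else logscale[s] = -arma::datum::inf;
    }
    const RevEig& e = eigs[cls];
    arma::mat W = e.A2 * C;
    arma::vec ex = arma::exp(e.lam * elen[i]);
    W.each_col() %= ex;
    arma::mat M = e.A1 * W;
    M.transform([](double x) { return x > 0.0 ? x : 0.0; });
    part[parent] %= M;
    part[child].reset();
  }
  arma::rowvec rootlik =
      arma::rowvec(root_prior.begin(), ns) * part[root - 1];
  NumericVector out(n_site);
  for (int s = 0; s < n_site; ++s) {
    double l = rootlik[s];
    out[s] = (l > 0.0 && std::isfinite(logscale[s]))
                 ? std::log(l) + logscale[s] : R_NegInf;
  }
  return out;
}

// Dense transition matrix exp(Qt) for a reversible Q; used by the simulators.
// [[Rcpp::export]]
NumericMatrix codon_pmat_cpp(NumericMatrix Q, NumericVector pi, double t) {
  int ns = pi.size();
  arma::mat Qm = as<arma::mat>(Q);
  arma::vec piv(pi.begin(), ns);
  RevEig e = rev_eig(Qm, piv);
  arma::mat P = e.A1 * arma::diagmat(arma::exp(e.lam * t)) * e.A2;
  P.transform([](double x) { return x > 0.0 ? x : 0.0; });
  // renormalize away eigen-roundoff so rows are exactly stochastic
  P.each_col() /= arma::sum(P, 1);
  return wrap(P);
}
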