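# Fitting and model comparison for the trait CTMC: multi-start ML, nested
# LRT, Metropolis-Hastings MCMC, stepping-stone marginal likelihoods, log
# Bayes factors and ancestral-constraint scans.

.RATE_LOWER <- 1e-6
.RATE_UPPER <- 1e3

#' Maximum-likelihood fit of a trait model
#'
#' Box-constrained quasi-Newton (`optim` L-BFGS-B) on log-rates with
#' multi-start: `n_starts` starting points drawn from the exponential prior
#' (mean `prior_mean`) plus one fixed start at 0.1 for every rate. Rates are
#' bounded in `[1e-6, 1e3]`. The model template's rate values are ignored;
#' its structure (independent vs dependent, classes, root prior) is used.
#'
#' @param tree Tagged `phylo`.
#' @param traits A [trait_table()].
#' @param model A [trait_model()] template.
#' @param constraints List of [node_constraint()]s.
#' @param n_starts Number of random starts (>= 1).
#' @param prior_mean Mean of the exponential used to draw starts.
#' @param init Optional numeric vector of rates used as an extra start
#'   (e.g. the independent-model solution when fitting the dependent model).
#' @return `trait_fit` object: `estimates` (named rates), `loglik`,
#'   `convergence` (TRUE when the best start converged), `n_par`.
#' @export
fit_trait_ml <- function(tree, traits, model, constraints = list(),
                         n_starts = 5, prior_mean = 0.1, init = NULL) {
  st <- unclass(traits)[tree$tip.label]
  if (!any(st %in% c("absent", "present")))
    stop("no informative tips (all states unknown)")
  fn <- .make_loglik_fn(tree, traits, model, constraints)
  lay <- .theta_layout(model, .tree_arrays(tree)$class_levels)
  npar <- lay$npar
  negll <- function(lth) -fn(exp(lth))
  starts <- list(rep(log(0.1), npar))
  for (i in seq_len(max(0, n_starts - 1)))
    starts[[length(starts) + 1]] <-
      log(pmin(pmax(rexp(npar, rate = 1 / prior_mean), .RATE_LOWER), .RATE_UPPER))
  if (!is.null(init))
    starts[[length(starts) + 1]] <- log(pmin(pmax(init, .RATE_LOWER), .RATE_UPPER))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, negll, method = "L-BFGS-B",
            lower = rep(log(.RATE_LOWER), npar),
            upper = rep(log(.RATE_UPPER), npar),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  est <- setNames(exp(best$par), lay$names)
  structure(list(estimates = est, loglik = -best$value,
                 convergence = best$convergence == 0, n_par = npar,
                 model = .model_with_theta(model, unname(est))),
            class = "trait_fit")
}

#' Likelihood-ratio test of the dependent vs independent trait model
#'
#' Statistic `2 * (logL_dep - logL_indep)` clamped at zero, compared with the
#' upper tail of chi-square with 1 df (the dependent model adds one free
#' parameter). A boundary-mixture option `0.5 chi2(0) + 0.5 chi2(1)` is
#' offered but off by default.
#'
#' @param ll_indep,ll_dep Log-likelihoods of the nested fits.
#' @param boundary_mixture Use the 50:50 mixture reference instead.
#' @export
lrt_dependent_vs_independent <- function(ll_indep, ll_dep,
                                         boundary_mixture = FALSE) {
  if (ll_dep < ll_indep - 1e-6)
    warning("dependent log-likelihood below independent: check convergence")
  stat <- max(0, 2 * (ll_dep - ll_indep))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary_mixture) p <- if (stat == 0) 1 else 0.5 * p
  list(statistic = stat, p_value = p, df = 1)
}

#' MCMC configuration
#'
#' Defaults follow common practice for this analysis: 1,010,000 iterations,
#' 10,000 burn-in, thinning 1,000 (so 1,000 retained samples) and
#' exponential priors with mean 0.1 on every rate.
#'
#' @param iterations,burnin,thinning Chain control (one single-parameter
#'   update per iteration).
#' @param prior_mean Exponential prior mean for all rates.
#' @param proposal_sd Initial random-walk sd on log-rates (adapted during
#'   burn-in only).
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @export
mcmc_config <- function(iterations = 1010000, burnin = 10000,
                        thinning = 1000, prior_mean = 0.1,
                        proposal_sd = 0.5, seed = NULL) {
  stopifnot(iterations > burnin, thinning >= 1, prior_mean > 0)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thinning = as.integer(thinning),
                 prior_mean = prior_mean, proposal_sd = proposal_sd,
                 seed = seed), class = "mcmc_config")
}

# crude autocorrelation-based effective sample size
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  a <- acf(x, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  pos <- which(a < 0.05)
  k <- if (length(pos)) pos[1] - 1 else length(a)
  n / (1 + 2 * sum(a[seq_len(k)]))
}

#' Metropolis-Hastings MCMC over the trait-model rates
#'
#' Gaussian random walk on log-rates, one parameter per iteration, with
#' exponential(`prior_mean`) priors on the natural scale. Proposal scales
#' adapt toward 44% acceptance during burn-in only, preserving detailed
#' balance afterwards. Identical seeds give identical chains.
#'
#' @inheritParams fit_trait_ml
#' @param config An [mcmc_config()].
#' @param init Optional starting rates (defaults to the prior mean).
#' @return `trait_mcmc` object: `samples` (data frame of thinned rates),
#'   `loglik` per sample, rate `medians`, per-sample `ratio_medians`
#'   (`q01:q10` and, when dependent, `q01:q10_delta`), `diagnostics`
#'   (acceptance rate and ESS per rate).
#' @export
run_trait_mcmc <- function(tree, traits, model, constraints = list(),
                           config = mcmc_config(), init = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  arr <- .tree_arrays(tree)
  lay <- .theta_layout(model, arr$class_levels)
  if (is.null(init)) init <- rep(config$prior_mean, lay$npar)
  rp_type <- match(model$root_prior,
                   c("stationary", "uniform", "fixed_absent", "fixed_present"))
  res <- trait_mcmc_cpp(arr$eparent, arr$echild, arr$elen, arr$eclass,
                        lay$gain_idx, lay$loss_idx,
                        .tip_partials(tree, traits),
                        .constraint_vector(tree, constraints),
                        rp_type, lay$root_class,
                        init, config$prior_mean, 1.0,
                        config$iterations, config$burnin, config$thinning,
                        rep(config$proposal_sd, lay$npar),
                        arr$n_tip, arr$n_node, arr$root)
  samples <- as.data.frame(res$samples)
  names(samples) <- lay$names
  if (res$acceptance < 0.1 || res$acceptance > 0.7)
    warning(sprintf("MCMC acceptance rate %.2f outside [0.1, 0.7]",
                    res$acceptance))
  ratios <- list(`q01:q10` = samples$q01 / samples$q10)
  if (lay$npar == 3L)
    ratios$`q01:q10_delta` <- samples$q01 / samples$q10_delta
  structure(list(samples = samples, loglik = res$loglik,
                 medians = vapply(samples, median, numeric(1)),
                 ratio_medians = vapply(ratios, median, numeric(1)),
                 diagnostics = list(acceptance = res$acceptance,
                                    ess = vapply(samples, .ess, numeric(1))),
                 config = config), class = "trait_mcmc")
}

#' Stepping-stone sampler configuration
#'
#' @param stones Number of stones K (>= 2; default 100).
#' @param iterations Iterations per stone (default 10,000).
#' @param alpha Power-schedule shape: `beta_k = (k/K)^(1/alpha)` (quantiles
#'   of Beta(alpha, 1); default 0.4).
#' @param burnin_frac Fraction of each stone discarded before averaging.
#' @param prior_mean,proposal_sd,seed As in [mcmc_config()].
#' @export
ss_config <- function(stones = 100, iterations = 10000, alpha = 0.4,
                      burnin_frac = 0.1, prior_mean = 0.1,
                      proposal_sd = 0.5, seed = NULL) {
  stopifnot(stones >= 2, iterations > 0, alpha > 0)
  structure(list(stones = as.integer(stones),
                 iterations = as.integer(iterations), alpha = alpha,
                 burnin_frac = burnin_frac, prior_mean = prior_mean,
                 proposal_sd = proposal_sd, seed = seed), class = "ss_config")
}

.logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Stepping-stone estimate of the log marginal likelihood
#'
#' Samples power posteriors `p(theta) L(theta)^beta_k` along the schedule
#' `beta_k = (k/K)^(1/alpha)` from the prior (`beta = 0`) up to the posterior
#' and accumulates the log marginal likelihood from per-stone importance
#' ratios. Chains are warm-started stone to stone.
#'
#' @inheritParams fit_trait_ml
#' @param config An [ss_config()].
#' @return `ss_logml` object: `logml`, per-stone `contributions`, `betas`.
#' @export
stepping_stone_logml <- function(tree, traits, model, constraints = list(),
                                 config = ss_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  arr <- .tree_arrays(tree)
  lay <- .theta_layout(model, arr$class_levels)
  tp <- .tip_partials(tree, traits)
  cv <- .constraint_vector(tree, constraints)
  rp_type <- match(model$root_prior,
                   c("stationary", "uniform", "fixed_absent", "fixed_present"))
  K <- config$stones
  betas <- (0:K / K)^(1 / config$alpha)
  n_burn <- max(1L, as.integer(config$burnin_frac * config$iterations))
  theta <- rep(config$prior_mean, lay$npar)
  sds <- rep(config$proposal_sd, lay$npar)
  contrib <- numeric(K)
  degenerate <- FALSE
  for (k in seq_len(K)) {
    res <- trait_mcmc_cpp(arr$eparent, arr$echild, arr$elen, arr$eclass,
                          lay$gain_idx, lay$loss_idx, tp, cv,
                          rp_type, lay$root_class,
                          theta, config$prior_mean, betas[k],
                          config$iterations, n_burn, 1L, sds,
                          arr$n_tip, arr$n_node, arr$root)
    dbeta_k <- betas[k + 1] - betas[k]
    contrib[k] <- .logmeanexp(dbeta_k * res$loglik)
    if (sd(res$loglik) == 0 && any(res$loglik != 0)) degenerate <- TRUE
    theta <- res$theta_end
    sds <- res$prop_sd
  }
  if (degenerate)
    warning("degenerate stone: all log-likelihood samples identical")
  structure(list(logml = sum(contrib), contributions = contrib,
                 betas = betas, config = config), class = "ss_logml")
}

#' Log Bayes factor between two marginal likelihoods
#'
#' `2 * (logML_1 - logML_2)` with the conventional evidence bands:
#' values <= 2 weak, in (2, 5] positive, > 5 strong.
#'
#' @param logml_1,logml_2 Log marginal likelihoods (finite).
#' @export
log_bayes_factor <- function(logml_1, logml_2) {
  stopifnot(is.finite(logml_1), is.finite(logml_2))
  value <- 2 * (logml_1 - logml_2)
  verdict <- if (value > 5) "strong" else if (value > 2) "positive" else "weak"
  list(value = value, verdict = verdict)
}

#' Constrained likelihoods for both states of an ancestral node
#'
#' Computes the pruning likelihood with the selected node fossilized to
#' `present` and to `absent`, and checks the partition identity
#' `L_present + L_absent = L_unconstrained`.
#'
#' @inheritParams fit_trait_ml
#' @param taxa Taxon set whose MRCA is scanned.
#' @return List with `loglik_present`, `loglik_absent`,
#'   `loglik_unconstrained`, `identity_ok`, `favored` state, `node`.
#' @export
ancestral_constraint_scan <- function(tree, traits, model, taxa) {
  node <- mrca_node(tree, taxa)
  st <- unclass(traits)[tree$tip.label]
  if (all(st == "unknown"))
    warning("constrained node carries no informative data")
  ll_u <- trait_loglik(tree, traits, model)
  ll_p <- trait_loglik(tree, traits, model,
                       list(node_constraint(taxa, "present")))
  ll_a <- trait_loglik(tree, traits, model,
                       list(node_constraint(taxa, "absent")))
  lsum <- .logmeanexp(c(ll_p, ll_a)) + log(2)
  list(loglik_present = ll_p, loglik_absent = ll_a,
       loglik_unconstrained = ll_u,
       identity_ok = abs(lsum - ll_u) < 1e-9,
       favored = if (ll_p >= ll_a) "present" else "absent",
       node = node)
}
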