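# Independent oracles and fixture builders shared across the suite.

# Brute-force trait likelihood: sum over every assignment of states to every
# node (tips weighted by their observation partials), product of transition
# probabilities over edges, times the root prior and constraint indicators.
# Deliberately independent of the pruning code path.
oracle_trait_loglik <- function(tree, traits, model, constraints = list()) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  st <- unclass(traits)[tree$tip.label]
  tipl <- lapply(st, function(s)
    switch(s, absent = c(1, 0), present = c(0, 1), unknown = c(1, 1)))
  cls <- tree$branch.class
  if (is.null(cls)) cls <- rep(model$default_class, nrow(tree$edge))
  loss_for <- function(cl)
    if (cl == model$delta_class && is_dependent(model)) model$q10_delta
    else model$q10
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_matrix(model$q01, loss_for(cls[e]), tree$edge.length[e]))
  rp <- switch(model$root_prior,
               stationary = c(model$q10, model$q01) / (model$q01 + model$q10),
               uniform = c(0.5, 0.5),
               fixed_absent = c(1, 0), fixed_present = c(0, 1))
  cvec <- rep(-1L, nn)
  for (con in constraints) {
    node <- mrca_node(tree, con$taxa)
    cvec[node] <- if (con$state == "present") 1L else 0L
  }
  tot <- 0
  for (mask in 0:(2^nn - 1)) {
    stv <- bitwAnd(bitwShiftR(mask, 0:(nn - 1)), 1)
    if (any(cvec >= 0 & stv != cvec)) next
    w <- rp[stv[nt + 1] + 1]
    for (i in seq_len(nt)) w <- w * tipl[[i]][stv[i] + 1]
    if (w == 0) next
    for (e in seq_len(nrow(tree$edge)))
      w <- w * P[[e]][stv[tree$edge[e, 1]] + 1, stv[tree$edge[e, 2]] + 1]
    tot <- tot + w
  }
  log(tot)
}

# 2-D trapezoid quadrature of the marginal likelihood for the 2-parameter
# (independent) model under exponential(prior_mean) priors.
oracle_quadrature_logml <- function(tree, traits, prior_mean = 0.1,
                                    n = 250, hi = 50) {
  g <- exp(seq(log(1e-6), log(hi), length.out = n))
  ll <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    ll[i, j] <- trait_loglik(tree, traits, trait_model(g[i], g[j]))
  pr <- outer(stats::dexp(g, 1 / prior_mean), stats::dexp(g, 1 / prior_mean))
  wi <- c(diff(g) / 2, 0) + c(0, diff(g) / 2)
  m <- max(ll)
  m + log(sum(outer(wi, wi) * pr * exp(ll - m)))
}

# random rooted tree with labels t1..tn, uniform branch lengths
random_tree <- function(n, max_len = 2) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, max_len))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

random_traits <- function(tree, p_unknown = 0.15) {
  states <- sample(c("absent", "present", "unknown"),
                   ape::Ntip(tree), replace = TRUE,
                   prob = c((1 - p_unknown) / 2, (1 - p_unknown) / 2,
                            p_unknown))
  trait_table(tree$tip.label, states)
}

# tag a random clade of the tree as "delta"
random_delta_tag <- function(tree) {
  nt <- ape::Ntip(tree)
  internal <- setdiff(seq_len(nt + tree$Nnode), c(seq_len(nt), nt + 1L))
  if (!length(internal)) return(tree)
  node <- if (length(internal) == 1) internal else sample(internal, 1)
  taxa <- ape::extract.clade(tree, node)$tip.label
  tag_branches(tree, branch_class_spec(
    list(list(class = "delta", taxa = taxa)), default = "alpha"))
}

# matrix-exponential transition probabilities (oracle for the closed forms)
oracle_expm <- function(Q, t) as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))

# star-tree codon likelihood by direct summation over the root state
oracle_star_codon_loglik <- function(edge_len, tip_states, Q, pi) {
  Ps <- lapply(edge_len, function(t) oracle_expm(Q, t))
  lik <- 0
  for (r in seq_along(pi)) {
    w <- pi[r]
    for (e in seq_along(edge_len)) {
      s <- tip_states[e]
      w <- w * if (s < 0) 1 else Ps[[e]][r, s + 1]
    }
    lik <- lik + w
  }
  log(lik)
}

# exact 99% binomial acceptance band for an empirical rejection rate
binom_band <- function(n, p = 0.05, level = 0.99) {
  a <- (1 - level) / 2
  c(stats::qbinom(a, n, p), stats::qbinom(1 - a, n, p)) / n
}
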