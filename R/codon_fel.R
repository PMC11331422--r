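# Site-level dN/dS (FEL) and between-partition contrasts (Contrast-FEL)
# under MG94xHKY. A shared nuisance stage fits kappa, a global omega and a
# tree-length scale; site tests then fit per-site synonymous (alpha_s) and
# nonsynonymous (beta_s, per partition for the contrast) rates on the tested
# branches with everything else held at the global fit.

.SITE_RATE_LOWER <- 1e-8
.SITE_RATE_UPPER <- 100

.codon_site_loglik <- function(arr, states_po_cols, Qlist, eclass_po,
                               elen, pi) {
  sum(codon_loglik_cpp(arr$eparent, arr$echild, elen, eclass_po,
                       Qlist, pi, states_po_cols, pi,
                       arr$n_tip, arr$n_node, arr$root))
}

#' Fit the shared (nuisance) parameters of the codon model
#'
#' Maximum-likelihood fit of kappa, a single global omega (`alpha = 1`,
#' `beta = omega` on all branches) and one tree-length scale, with F3x4
#' frequencies computed from the observed position-specific nucleotide
#' counts and held fixed. These parameters are frozen before any site test.
#'
#' @param aln A [codon_alignment()] (>= 3 sequences, >= 2 variable sites).
#' @return `codon_nuisance` object: `kappa`, `omega`, `scale`, `pi_pos`,
#'   `pi_codon`, `parts` (synonymous/nonsynonymous generator parts),
#'   `norm_const` (the shared normalization), `loglik`.
#' @export
fit_global_nuisance <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln$ids) < 3) stop("need at least 3 sequences")
  nvar <- sum(apply(aln$states, 2, function(col) {
    s <- unique(col[col >= 0]); length(s) > 1
  }))
  if (nvar < 2) stop("no signal: fewer than 2 variable sites")
  fr <- f3x4_frequencies(aln$seqs)
  tree <- aln$tree
  tree$branch.class <- rep("all", nrow(tree$edge))
  arr <- .tree_arrays(tree, "all")
  states <- aln$states[tree$tip.label, , drop = FALSE]
  negll <- function(par) {
    kappa <- exp(par[1]); omega <- exp(par[2]); scale <- exp(par[3])
    parts <- mg94_parts(kappa, fr$pi_pos)
    Q <- parts$Rsyn + omega * parts$Rnon
    Q <- Q / .mg94_rate(Q, parts$pi_codon)
    ll <- .codon_site_loglik(arr, states, list(Q), arr$eclass,
                             arr$elen * scale, parts$pi_codon)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  fit <- optim(c(log(2), log(0.5), 0), negll, method = "L-BFGS-B",
               lower = c(log(0.1), log(1e-4), log(1e-3)),
               upper = c(log(50), log(10), log(1e3)),
               control = list(maxit = 300))
  kappa <- exp(fit$par[1]); omega <- exp(fit$par[2]); scale <- exp(fit$par[3])
  parts <- mg94_parts(kappa, fr$pi_pos)
  norm_const <- .mg94_rate(parts$Rsyn + omega * parts$Rnon, parts$pi_codon)
  structure(list(kappa = kappa, omega = omega, scale = scale,
                 pi_pos = fr$pi_pos, pi_codon = parts$pi_codon,
                 parts = parts, norm_const = norm_const,
                 loglik = -fit$value, convergence = fit$convergence == 0),
            class = "codon_nuisance")
}

# site Q with the nuisance normalization frozen
.site_Q <- function(nuis, alpha, beta)
  (alpha * nuis$parts$Rsyn + beta * nuis$parts$Rnon) / nuis$norm_const

.bg_Q <- function(nuis) .site_Q(nuis, 1, nuis$omega)

# resolve a tested-branch selector to a logical over the original edge order
.tested_edges <- function(aln, branches) {
  ne <- nrow(aln$tree$edge)
  if (is.character(branches) && length(branches) == 1L) {
    cls <- .partition_edge_classes(aln)
    sel <- cls == branches
    if (!any(sel)) stop("no branches in partition '", branches, "'")
    return(sel)
  }
  if (is.logical(branches) && length(branches) == ne) return(branches)
  if (is.numeric(branches)) return(seq_len(ne) %in% branches)
  stop("branches must be a partition label, logical edge mask or indices")
}

.snap0 <- function(x) ifelse(x <= 2 * .SITE_RATE_LOWER, 0, x)

#' FEL-style test of per-site selection on a branch subset
#'
#' Fits site-specific synonymous (`alpha_s`) and nonsynonymous (`beta_s`)
#' rates on the tested branches (other branches stay at the globally fitted
#' omega) and tests `beta_s = alpha_s` against the free model by a 1-df
#' likelihood-ratio test. dN/dS is `beta_s / alpha_s`.
#'
#' @param aln A [codon_alignment()].
#' @param site Codon site index (1-based).
#' @param branches Tested branch subset: a partition label (`"alpha"` or
#'   `"delta"`), a logical edge mask, or edge indices.
#' @param nuisance A [fit_global_nuisance()] result (fitted if `NULL`).
#' @return `site_test` object with `alpha_hat`, `beta_hat`, `dnds`,
#'   `statistic`, `p_value`, `direction` (`"dN<dS"`/`"dN>dS"`), flags.
#' @export
fel_site_test <- function(aln, site, branches, nuisance = NULL) {
  if (is.null(nuisance)) nuisance <- fit_global_nuisance(aln)
  tested <- .tested_edges(aln, branches)
  tree <- aln$tree
  arr <- .tree_arrays(tree, unique(tree$branch.class %||% "alpha"))
  states <- aln$states[tree$tip.label, site, drop = FALSE]
  eclass_po <- ifelse(tested[arr$edge_order], 1L, 2L)
  elen <- arr$elen * nuisance$scale
  pi <- nuisance$pi_codon
  obs <- states[states >= 0]
  if (length(unique(obs)) <= 1L) {
    return(structure(list(site_label = aln$site_labels[site],
                          alpha_hat = 0, beta_hat = 0, dnds = NA_real_,
                          statistic = 0, p_value = NA_real_,
                          direction = NA_character_, test = "FEL",
                          untestable = TRUE), class = "site_test"))
  }
  ll_at <- function(a, b) {
    Qs <- .site_Q(nuisance, a, b)
    .codon_site_loglik(arr, states, list(Qs, .bg_Q(nuisance)),
                       eclass_po, elen, pi)
  }
  negll2 <- function(par) {
    v <- -ll_at(exp(par[1]), exp(par[2])); if (!is.finite(v)) 1e10 else v
  }
  lb <- log(.SITE_RATE_LOWER); ub <- log(.SITE_RATE_UPPER)
  best <- NULL
  for (s in list(c(0, log(max(nuisance$omega, 1e-3))), c(0, log(0.05)))) {
    f <- tryCatch(optim(s, negll2, method = "L-BFGS-B", lower = lb,
                        upper = ub, control = list(maxit = 200)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  oneq <- optimize(function(lr) {
    v <- -ll_at(exp(lr), exp(lr)); if (!is.finite(v)) 1e10 else v
  }, c(lb, ub))
  ll_alt <- -best$value
  ll_null <- -oneq$objective
  # statistics below optimizer resolution are treated as exactly null
  stat <- max(0, 2 * (ll_alt - ll_null))
  if (stat < 1e-4) stat <- 0
  a_hat <- exp(best$par[1]); b_hat <- .snap0(exp(best$par[2]))
  structure(list(site_label = aln$site_labels[site],
                 alpha_hat = a_hat, beta_hat = b_hat,
                 dnds = if (a_hat <= 2 * .SITE_RATE_LOWER) NA_real_
                        else b_hat / a_hat,
                 statistic = stat,
                 p_value = pchisq(stat, 1, lower.tail = FALSE),
                 direction = if (b_hat < a_hat) "dN<dS" else "dN>dS",
                 test = "FEL", untestable = FALSE), class = "site_test")
}

#' Contrast-FEL-style test of partition-specific nonsynonymous rates
#'
#' Fits a shared per-site synonymous rate and partition-specific
#' nonsynonymous rates (`beta_alpha`, `beta_delta`) over the whole tree
#' (branch partition by clade membership, stems included) and tests
#' `beta_alpha = beta_delta` by a 1-df likelihood-ratio test.
#'
#' @inheritParams fel_site_test
#' @return `site_test` object with per-partition `beta_hat` and `dnds`,
#'   their `ratio` (delta/alpha), `statistic`, `p_value`, flags.
#' @export
contrast_fel_site_test <- function(aln, site, nuisance = NULL) {
  if (is.null(nuisance)) nuisance <- fit_global_nuisance(aln)
  if (!all(c("alpha", "delta") %in% aln$partition))
    stop("both partitions must be non-empty")
  tree <- aln$tree
  cls <- .partition_edge_classes(aln)
  tree$branch.class <- cls
  arr <- .tree_arrays(tree, c("alpha", "delta"))
  states <- aln$states[tree$tip.label, site, drop = FALSE]
  elen <- arr$elen * nuisance$scale
  pi <- nuisance$pi_codon
  novar <- vapply(c("alpha", "delta"), function(p) {
    tips <- names(aln$partition)[aln$partition == p]
    s <- states[match(tips, tree$tip.label), 1]
    length(unique(s[s >= 0])) <= 1L
  }, logical(1))
  ll_at <- function(a, ba, bd) {
    .codon_site_loglik(arr, states,
                       list(.site_Q(nuisance, a, ba),
                            .site_Q(nuisance, a, bd)),
                       arr$eclass, elen, pi)
  }
  lb <- log(.SITE_RATE_LOWER); ub <- log(.SITE_RATE_UPPER)
  negll3 <- function(par) {
    v <- -ll_at(exp(par[1]), exp(par[2]), exp(par[3]))
    if (!is.finite(v)) 1e10 else v
  }
  negll2 <- function(par) {
    v <- -ll_at(exp(par[1]), exp(par[2]), exp(par[2]))
    if (!is.finite(v)) 1e10 else v
  }
  om <- log(max(nuisance$omega, 1e-3))
  best3 <- NULL
  for (s in list(c(0, om, om), c(0, log(0.05), log(0.5)))) {
    f <- tryCatch(optim(s, negll3, method = "L-BFGS-B", lower = lb,
                        upper = ub, control = list(maxit = 300)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best3) || f$value < best3$value)) best3 <- f
  }
  best2 <- optim(c(0, om), negll2, method = "L-BFGS-B", lower = lb,
                 upper = ub, control = list(maxit = 300))
  ll_alt <- -best3$value
  ll_null <- -best2$value
  stat <- max(0, 2 * (ll_alt - ll_null))
  if (stat < 1e-4) stat <- 0
  a_hat <- exp(best3$par[1])
  b_a <- .snap0(exp(best3$par[2])); b_d <- .snap0(exp(best3$par[3]))
  flagged <- any(novar)
  p <- if (flagged) 1 else pchisq(stat, 1, lower.tail = FALSE)
  dnds <- if (a_hat <= 2 * .SITE_RATE_LOWER) c(alpha = NA_real_,
                                               delta = NA_real_)
          else c(alpha = b_a / a_hat, delta = b_d / a_hat)
  structure(list(site_label = aln$site_labels[site],
                 alpha_hat = a_hat,
                 beta_hat = c(alpha = b_a, delta = b_d),
                 dnds = dnds,
                 ratio = if (b_a > 0) b_d / b_a else NA_real_,
                 statistic = if (flagged) 0 else stat, p_value = p,
                 test = "Contrast-FEL",
                 no_variation = novar, flagged = flagged,
                 untestable = FALSE), class = "site_test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
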