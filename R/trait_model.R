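# Two-state CTMC trait model: rate containers, transition probabilities and
# the pruning likelihood (C++ kernel) with node fossilization.

#' Two-state trait model with an optional class-specific loss rate
#'
#' State 0 = site absent, state 1 = site present. `q01` is the gain rate and
#' `q10` the loss rate (events per unit branch length). When `q10_delta` is
#' supplied the model is "dependent": branches tagged with `delta_class`
#' lose the trait at `q10_delta` instead of `q10` (the gain rate is shared).
#'
#' @param q01,q10 Gain and loss rates (> 0).
#' @param q10_delta Optional loss rate for `delta_class` branches.
#' @param default_class,delta_class Branch class names.
#' @param root_prior `"stationary"` (default; the stationary distribution of
#'   the default-class rates), `"uniform"`, `"fixed_absent"` or
#'   `"fixed_present"`.
#' @export
trait_model <- function(q01, q10, q10_delta = NULL,
                        default_class = "alpha", delta_class = "delta",
                        root_prior = c("stationary", "uniform",
                                       "fixed_absent", "fixed_present")) {
  root_prior <- match.arg(root_prior)
  rates <- c(q01 = q01, q10 = q10)
  if (!is.null(q10_delta)) rates <- c(rates, q10_delta = q10_delta)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("rates must be strictly positive and finite")
  structure(list(q01 = q01, q10 = q10, q10_delta = q10_delta,
                 default_class = default_class, delta_class = delta_class,
                 root_prior = root_prior),
            class = "trait_model")
}

#' @rdname trait_model
#' @param x Object.
#' @export
is_dependent <- function(x) !is.null(x$q10_delta)

#' Closed-form 2x2 transition matrix of the binary chain
#'
#' `P(t) = exp(Qt)` with `Q = [[-q01, q01], [q10, -q10]]`, computed via
#' `exp(-(q01+q10) t)`. Rows/columns are ordered (absent, present).
#'
#' @param gain,loss Rates (> 0).
#' @param t Branch length (>= 0).
#' @export
transition_matrix <- function(gain, loss, t) {
  if (t < 0) stop("negative branch length")
  stopifnot(gain > 0, loss > 0)
  s <- gain + loss
  e <- exp(-s * t)
  matrix(c((loss + gain * e) / s, (gain - gain * e) / s,
           (loss - loss * e) / s, (gain + loss * e) / s),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("absent", "present"), c("absent", "present")))
}

#' Fossilize an internal node (or tip) to a fixed state
#'
#' @param taxa Taxon set whose MRCA is the constrained node.
#' @param state `"absent"` or `"present"`.
#' @export
node_constraint <- function(taxa, state = c("absent", "present")) {
  state <- match.arg(state)
  structure(list(taxa = taxa, state = state), class = "node_constraint")
}

# per-node constraint codes for the kernels: -1 free, 0 absent, 1 present
.constraint_vector <- function(tree, constraints) {
  nn <- ape::Ntip(tree) + tree$Nnode
  v <- rep(-1L, nn)
  for (con in constraints) {
    stopifnot(inherits(con, "node_constraint"))
    node <- mrca_node(tree, con$taxa)
    if (is.null(node) || is.na(node)) stop("constraint node not found")
    v[node] <- if (con$state == "present") 1L else 0L
  }
  v
}

# tip partial likelihoods: absent (1,0), present (0,1), unknown (1,1)
.tip_partials <- function(tree, traits) {
  .validate_traits(tree, traits)
  st <- unclass(traits)[tree$tip.label]
  m <- matrix(1, nrow = length(st), ncol = 2)
  m[st == "absent", 2] <- 0
  m[st == "present", 1] <- 0
  m
}

# rate matrix (n_class x 2: gain, loss) over the tree's class levels
.class_rates <- function(model, class_levels) {
  m <- matrix(NA_real_, nrow = length(class_levels), ncol = 2)
  for (k in seq_along(class_levels)) {
    cl <- class_levels[k]
    if (cl == model$delta_class && is_dependent(model)) {
      m[k, ] <- c(model$q01, model$q10_delta)
    } else {
      m[k, ] <- c(model$q01, model$q10)
    }
  }
  m
}

.root_prior_vec <- function(model) {
  switch(model$root_prior,
         stationary = {
           s <- model$q01 + model$q10
           c(model$q10 / s, model$q01 / s)
         },
         uniform = c(0.5, 0.5),
         fixed_absent = c(1, 0),
         fixed_present = c(0, 1))
}

#' Pruning log-likelihood of a trait table under a trait model
#'
#' Felsenstein pruning over the two-state chain; `unknown` tips contribute
#' partials (1,1), constraints zero out the disallowed state at the
#' constrained node after its children are combined, and the root partials
#' are combined with the model's root prior.
#'
#' @param tree `phylo`; branch classes (if any) in `tree$branch.class`.
#' @param traits A [trait_table()] covering every tip.
#' @param model A [trait_model()].
#' @param constraints List of [node_constraint()]s.
#' @export
trait_loglik <- function(tree, traits, model, constraints = list()) {
  arr <- .tree_arrays(tree)
  trait_loglik_cpp(arr$eparent, arr$echild, arr$elen, arr$eclass,
                   .class_rates(model, arr$class_levels),
                   .tip_partials(tree, traits),
                   .constraint_vector(tree, constraints),
                   .root_prior_vec(model),
                   arr$n_tip, arr$n_node, arr$root)
}

# theta <-> model plumbing for fitting and MCMC.
# theta = (q01, q10) or (q01, q10, q10_delta); per-class (gain, loss) index
# pairs into theta.
.theta_layout <- function(model, class_levels) {
  npar <- if (is_dependent(model)) 3L else 2L
  gain_idx <- rep(1L, length(class_levels))
  loss_idx <- ifelse(class_levels == model$delta_class & npar == 3L, 3L, 2L)
  root_class <- match(model$default_class, class_levels)
  if (is.na(root_class)) root_class <- 1L
  list(npar = npar, gain_idx = gain_idx, loss_idx = as.integer(loss_idx),
       root_class = as.integer(root_class),
       names = c("q01", "q10", if (npar == 3L) "q10_delta"))
}

.model_with_theta <- function(model, theta) {
  model$q01 <- theta[1]
  model$q10 <- theta[2]
  if (is_dependent(model)) model$q10_delta <- theta[3]
  model
}

# fast likelihood-as-a-function-of-theta used by optimizers
.make_loglik_fn <- function(tree, traits, model, constraints) {
  arr <- .tree_arrays(tree)
  tp <- .tip_partials(tree, traits)
  cv <- .constraint_vector(tree, constraints)
  lay <- .theta_layout(model, arr$class_levels)
  rp_type <- match(model$root_prior,
                   c("stationary", "uniform", "fixed_absent", "fixed_present"))
  function(theta) {
    rates <- cbind(theta[lay$gain_idx], theta[lay$loss_idx])
    rp <- if (rp_type == 1L) {
      a <- rates[lay$root_class, 1]; b <- rates[lay$root_class, 2]
      c(b, a) / (a + b)
    } else if (rp_type == 2L) c(0.5, 0.5)
    else if (rp_type == 3L) c(1, 0) else c(0, 1)
    trait_loglik_cpp(arr$eparent, arr$echild, arr$elen, arr$eclass,
                     rates, tp, cv, rp, arr$n_tip, arr$n_node, arr$root)
  }
}
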