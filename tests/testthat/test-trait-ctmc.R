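test_that("transition_matrix matches the matrix exponential", {
  expect_equal(transition_matrix(0.3, 0.7, 0), diag(2), ignore_attr = TRUE)
  # stationary limit with symmetric rates
  expect_equal(unname(transition_matrix(1, 1, 1e6)),
               matrix(0.5, 2, 2), tolerance = 1e-12)
  Q <- matrix(c(-1, 1, 2, -2), 2, byrow = TRUE)
  expect_equal(unname(transition_matrix(1, 2, 0.7)),
               oracle_expm(Q, 0.7), tolerance = 1e-12)
  expect_error(transition_matrix(1, 2, -1), "negative")
  # rows sum to one for random rates
  set.seed(2)
  for (i in 1:10) {
    P <- transition_matrix(rexp(1), rexp(1), rexp(1))
    expect_equal(unname(rowSums(P)), c(1, 1), tolerance = 1e-12)
  }
})

test_that("pruning equals brute-force enumeration (independent + dependent)", {
  set.seed(101)
  for (i in 1:30) {
    tr <- random_delta_tag(random_tree(sample(3:6, 1)))
    tt <- random_traits(tr)
    dep <- i %% 2 == 0
    m <- trait_model(rexp(1, 5) + 0.01, rexp(1, 5) + 0.01,
                     q10_delta = if (dep) rexp(1, 5) + 0.01,
                     root_prior = sample(c("stationary", "uniform"), 1))
    expect_equal(trait_loglik(tr, tt, m), oracle_trait_loglik(tr, tt, m),
                 tolerance = 1e-10)
  }
})

test_that("degenerate cases: flat data, stationary symmetry", {
  tr <- read_newick("((A:1,B:1):0.5,C:1.5);")
  m <- trait_model(0.4, 0.9)
  ttu <- trait_table(c("A", "B", "C"), rep("unknown", 3))
  expect_equal(trait_loglik(tr, ttu, m), 0)
  # one informative tip on a zero-length branch, symmetric stationary root
  tr2 <- read_newick("(A:0,B:0);")
  tt2 <- trait_table(c("A", "B"), c("present", "unknown"))
  expect_equal(trait_loglik(tr2, tt2, trait_model(0.5, 0.5)), log(0.5))
})

test_that("likelihood is invariant to child order and unknown-tip grafts", {
  m <- trait_model(0.3, 0.8)
  tt <- trait_table(c("A", "B", "C"), c("present", "absent", "present"))
  l1 <- trait_loglik(read_newick("((A:1,B:2):0.5,C:1.5);"), tt, m)
  l2 <- trait_loglik(read_newick("(C:1.5,(B:2,A:1):0.5);"), tt, m)
  expect_equal(l1, l2, tolerance = 1e-12)
  # splitting a branch in two (joined by an unknown-tip node) changes nothing:
  # the unknown tip contributes a factor of one through any branch length
  tt3 <- trait_table(c("A", "B", "C", "U"),
                     c("present", "absent", "present", "unknown"))
  l3 <- trait_loglik(read_newick("((A:1,B:2):0.5,(C:0.75,U:9):0.75);"),
                     tt3, m)
  expect_equal(l3, l1, tolerance = 1e-12)
})

test_that("constraints partition the likelihood and order marginals", {
  set.seed(55)
  m <- trait_model(0.25, 0.6)
  for (i in 1:10) {
    tr <- random_tree(10)
    tt <- random_traits(tr, p_unknown = 0.1)
    taxa <- sample(tr$tip.label, 3)
    sc <- ancestral_constraint_scan(tr, tt, m, taxa)
    lsum <- log(exp(sc$loglik_present) + exp(sc$loglik_absent))
    expect_equal(lsum, sc$loglik_unconstrained, tolerance = 1e-9)
    # the favored state costs less log-likelihood than the other
    drop_fav <- sc$loglik_unconstrained -
      max(sc$loglik_present, sc$loglik_absent)
    drop_oth <- sc$loglik_unconstrained -
      min(sc$loglik_present, sc$loglik_absent)
    expect_lte(drop_fav, drop_oth)
  }
})

test_that("constraints agree with the enumeration oracle", {
  set.seed(77)
  for (i in 1:8) {
    tr <- random_tree(5)
    tt <- random_traits(tr)
    m <- trait_model(0.3, 0.2)
    con <- list(node_constraint(sample(tr$tip.label, 2), "present"))
    expect_equal(trait_loglik(tr, tt, m, con),
                 oracle_trait_loglik(tr, tt, m, con), tolerance = 1e-10)
  }
})

test_that("ML fitting respects nesting and boundary behavior", {
  set.seed(8)
  # dependent logL never below independent logL
  for (i in 1:5) {
    tr <- random_delta_tag(random_tree(25))
    tt <- random_traits(tr, p_unknown = 0)
    fi <- fit_trait_ml(tr, tt, trait_model(0.1, 0.1), n_starts = 2)
    fd <- fit_trait_ml(tr, tt, trait_model(0.1, 0.1, q10_delta = 0.1),
                       n_starts = 2, init = c(fi$estimates, fi$estimates[2]))
    expect_gte(fd$loglik, fi$loglik - 1e-6)
  }
  # all-present data drives the loss rate to the lower bound
  tr <- random_tree(30)
  ttp <- trait_table(tr$tip.label, rep("present", 30))
  f <- fit_trait_ml(tr, ttp, trait_model(0.1, 0.1), n_starts = 2)
  expect_lt(f$estimates["q10"], 1e-5)
  expect_error(fit_trait_ml(tr, trait_table(tr$tip.label,
                                            rep("unknown", 30)),
                            trait_model(0.1, 0.1)), "no informative")
})

test_that("the LRT clamps at zero and uses chi-square(1)", {
  expect_equal(lrt_dependent_vs_independent(-10, -10),
               list(statistic = 0, p_value = 1, df = 1))
  r <- lrt_dependent_vs_independent(-10, -10 + 3.841459 / 2)
  expect_equal(r$p_value, 0.05, tolerance = 1e-4)
  expect_warning(lrt_dependent_vs_independent(-9, -10), "below")
  r2 <- lrt_dependent_vs_independent(-10, -8, boundary_mixture = TRUE)
  expect_equal(r2$p_value,
               0.5 * pchisq(4, 1, lower.tail = FALSE))
})

test_that("log_bayes_factor reports the conventional evidence bands", {
  expect_equal(log_bayes_factor(-3, -3), list(value = 0, verdict = "weak"))
  expect_equal(log_bayes_factor(-1, -3.45)$value, 4.9)
  expect_equal(log_bayes_factor(-1, -3.45)$verdict, "positive")
  expect_equal(log_bayes_factor(0, -2.75)$verdict, "strong")
  expect_error(log_bayes_factor(Inf, 0))
})
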