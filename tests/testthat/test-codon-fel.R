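pi_uni <- matrix(0.25, 3, 4, dimnames = list(NULL, c("T", "C", "A", "G")))
pi_skew <- matrix(c(.3, .2, .3, .2,
                    .25, .25, .25, .25,
                    .15, .35, .2, .3), 3, 4, byrow = TRUE,
                  dimnames = list(NULL, c("T", "C", "A", "G")))

test_that("the MG94 generator has the defining structural properties", {
  parts <- mg94_parts(2.5, pi_skew)
  tab <- paralogsel:::.codon_tables()
  Q <- mg94_generator(2.5, 1, 0.4, pi_skew)
  pi <- attr(Q, "pi_codon")
  # multi-nucleotide changes carry zero rate
  cm <- tab$codon_mat
  for (i in c(1, 17, 40)) for (j in c(5, 23, 61)) {
    if (sum(cm[i, ] != cm[j, ]) > 1) expect_equal(Q[i, j], 0)
  }
  # beta = 0 silences all amino-acid-changing flux
  Q0 <- mg94_generator(2.5, 1, 0, pi_skew)
  diffaa <- outer(tab$aa, tab$aa, "!=")
  expect_true(all(Q0[diffaa] == 0))
  # generator rows sum to zero; stationarity; detailed balance
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_lt(max(abs(pi %*% Q)), 1e-10)
  D <- diag(pi) %*% Q
  expect_lt(max(abs(D - t(D))), 1e-12)
  # P(t) is stochastic and matches the generic matrix exponential
  Qn <- mg94_generator(2.5, 1, 0.4, pi_skew, normalize = TRUE)
  P <- paralogsel:::codon_pmat_cpp(Qn, pi, 0.7)
  expect_equal(P, oracle_expm(Qn, 0.7), tolerance = 1e-9)
  expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-12)
})

test_that("F3x4 frequencies come out uniform on uniform composition", {
  fr <- f3x4_frequencies(c("TTTCCCAAAGGG", "CCCAAAGGGTTT",
                           "AAAGGGTTTCCC", "GGGTTTCCCAAA"))
  expect_equal(unname(fr$pi_pos), matrix(0.25, 3, 4), tolerance = 1e-12)
  expect_equal(fr$pi_codon, rep(1 / 61, 61), tolerance = 1e-12)
  # gaps and ambiguity are simply not counted
  # gaps and ambiguity are not counted; frequencies are floored away from 0
  fr2 <- f3x4_frequencies(c("TTT---", "TTTNNN"))
  expect_gt(min(fr2$pi_pos[, "T"]), 0.999)
  expect_true(all(fr2$pi_pos > 0))
})

test_that("codon pruning matches star-tree enumeration", {
  set.seed(31)
  tree <- read_newick("(A:0.3,B:0.5,C:0.2);")
  tree$branch.class <- rep("alpha", 3)
  arr <- paralogsel:::.tree_arrays(tree, "alpha")
  for (i in 1:5) {
    Q <- mg94_generator(runif(1, 1, 5), 1, runif(1), pi_skew,
                        normalize = TRUE)
    pi <- attr(Q, "pi_codon")
    states <- c(sample(0:60, 2), -1L)[sample(3)]  # one ambiguous tip
    sm <- matrix(states, ncol = 1)
    ll <- paralogsel:::codon_loglik_cpp(arr$eparent, arr$echild, arr$elen,
                                        arr$eclass, list(Q), pi, sm, pi,
                                        arr$n_tip, arr$n_node, arr$root)
    # oracle edge order must follow the postorder children
    expect_equal(ll, oracle_star_codon_loglik(arr$elen, states[arr$echild],
                                              Q, pi), tolerance = 1e-8)
  }
})

test_that("nuisance fit recovers kappa and ignores sequence duplication", {
  tree <- simulate_tree(40, total_length = 80, seed = 301)
  aln <- simulate_codon_alignment(tree, 100, kappa = 3, omega_alpha = 0.5,
                                  seed = 302)
  nuis <- fit_global_nuisance(aln)
  expect_gt(nuis$kappa, 2.4)
  expect_lt(nuis$kappa, 3.6)
  expect_gt(nuis$omega, 0.25)
  expect_lt(nuis$omega, 0.9)
  # grafting a zero-length duplicate of every sequence multiplies each tip
  # partial by P(0) = I, so the fitted kappa is unchanged
  tree2 <- tree
  for (tp in tree$tip.label) {
    tree2 <- ape::bind.tree(tree2, read_newick(paste0("(", tp, "d:0);")),
                            where = match(tp, tree2$tip.label),
                            position = 1e-8)
  }
  tree2$edge.length <- pmax(tree2$edge.length, 0)
  seqs2 <- c(aln$seqs, setNames(aln$seqs, paste0(names(aln$seqs), "d")))
  part2 <- setNames(rep("alpha", length(seqs2)), names(seqs2))
  aln2 <- codon_alignment(seqs2, tree2, part2)
  nuis2 <- fit_global_nuisance(aln2)
  expect_equal(nuis2$kappa, nuis$kappa, tolerance = 0.02)
  expect_error(fit_global_nuisance(
    codon_alignment(setNames(rep("TTTTTT", 3), c("a", "b", "c")),
                    read_newick("(a:1,b:1,c:1);"),
                    setNames(rep("alpha", 3), c("a", "b", "c")))),
    "no signal")
})

test_that("FEL flags invariant sites and finds purely synonymous variation", {
  tree <- read_newick(paste0("((s1:0.4,s2:0.4):0.2,(s3:0.4,s4:0.4):0.2,",
                             "(s5:0.4,s6:0.4):0.2);"))
  ids <- paste0("s", 1:6)
  # site 1: Phe TTT/TTC synonymous toggling; site 2: invariant;
  # site 3: syn variation (Leu CTT/CTC); site 4: nonsyn variation
  seqs <- setNames(c("TTTATGCTTAAA", "TTCATGCTCAAA", "TTTATGCTTGAA",
                     "TTCATGCTCAAA", "TTTATGCTTGAA", "TTCATGCTCAAA"), ids)
  part <- setNames(rep("alpha", 6), ids)
  aln <- codon_alignment(seqs, tree, part)
  nuis <- fit_global_nuisance(aln)
  r1 <- fel_site_test(aln, 1, rep(TRUE, nrow(tree$edge)), nuis)
  expect_false(r1$untestable)
  expect_equal(r1$beta_hat, 0)
  expect_equal(r1$dnds, 0)
  expect_equal(r1$direction, "dN<dS")
  r2 <- fel_site_test(aln, 2, rep(TRUE, nrow(tree$edge)), nuis)
  expect_true(r2$untestable)
  expect_equal(r2$alpha_hat, 0)
  # determinism: a duplicated column yields identical results
  r3a <- fel_site_test(aln, 3, rep(TRUE, nrow(tree$edge)), nuis)
  seqs2 <- setNames(paste0(seqs, substr(seqs, 7, 9)), ids)
  aln2 <- codon_alignment(seqs2, tree, part)
  r3b <- fel_site_test(aln2, 5, rep(TRUE, nrow(tree$edge)), nuis)
  expect_equal(r3a$alpha_hat, r3b$alpha_hat, tolerance = 1e-6)
  expect_equal(r3a$p_value, r3b$p_value, tolerance = 1e-6)
})

test_that("contrast test is null on mirrored partitions and label-symmetric", {
  tree <- read_newick("((a1:0.1,a2:0.3):0.1,(d1:0.1,d2:0.3):0.1);")
  seqs <- c(a1 = "TTTAAACTTGGG", a2 = "TTCAAGATTGCG",
            d1 = "TTTAAACTTGGG", d2 = "TTCAAGATTGCG")
  part <- setNames(c("alpha", "alpha", "delta", "delta"), names(seqs))
  aln <- codon_alignment(seqs, tree, part)
  nuis <- fit_global_nuisance(aln)
  ct <- contrast_fel_site_test(aln, 3, nuis)
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p_value, 1)
  # swapping the partition labels inverts the ratio, p unchanged
  part_sw <- setNames(c("delta", "delta", "alpha", "alpha"), names(seqs))
  aln_sw <- codon_alignment(seqs, tree, part_sw)
  ct_sw <- contrast_fel_site_test(aln_sw, 3, fit_global_nuisance(aln_sw))
  expect_equal(ct_sw$p_value, ct$p_value, tolerance = 1e-6)
})

test_that("per-site dN/dS estimates track the simulated omega", {
  tree <- simulate_tree(40, total_length = 80, seed = 311)
  for (om in c(0.1, 1)) {
    aln <- simulate_codon_alignment(tree, 40, omega_alpha = om,
                                    seed = 312 + round(10 * om))
    nuis <- fit_global_nuisance(aln)
    ests <- vapply(seq_len(10), function(s) {
      r <- fel_site_test(aln, s, rep(TRUE, nrow(tree$edge)), nuis)
      if (is.na(r$dnds)) NA_real_ else r$dnds
    }, numeric(1))
    expect_gt(median(ests, na.rm = TRUE), om / 3)
    expect_lt(median(ests, na.rm = TRUE), om * 3)
  }
})
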