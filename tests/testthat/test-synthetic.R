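test_that("simulate_tree is seed-stable and tags a delta clade", {
  tr <- simulate_tree(10, seed = 1)
  expect_equal(ape::Ntip(tr), 10)
  expect_equal(tr$Nnode, 9)     # binary rooted tree
  expect_identical(write_newick(simulate_tree(10, seed = 1)),
                   write_newick(tr))
  expect_error(simulate_tree(2), "n_tips")
  tr2 <- simulate_tree(200, delta_fraction = 0.5, seed = 2)
  nd <- length(attr(tr2, "delta_tips"))
  expect_gte(nd, 80)
  expect_lte(nd, 120)
  # the clade rule: delta branches are exactly those with all tips in the clade
  spec_cls <- tr2$branch.class
  expect_length(spec_cls, nrow(tr2$edge))
  expect_setequal(unique(spec_cls), c("alpha", "delta"))
  rescaled <- simulate_tree(20, total_length = 12.5, seed = 3)
  expect_equal(sum(rescaled$edge.length), 12.5)
})

test_that("trait simulation follows the chain law", {
  # near-zero rates: every tip inherits the root state
  tr <- simulate_tree(30, seed = 4)
  m0 <- trait_model(1e-6, 1e-6, root_prior = "fixed_present")
  tt <- simulate_traits(tr, m0, seed = 5)
  expect_true(all(unclass(tt) == "present"))
  # long branches, symmetric rates: tip frequency near 1/2
  trl <- simulate_tree(4000, seed = 6)
  trl$edge.length <- trl$edge.length * 50
  ttl <- simulate_traits(trl, trait_model(1, 1), seed = 7)
  frac <- mean(unclass(ttl) == "present")
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
  # single-branch transition frequencies match the transition matrix
  two <- read_newick("(A:1.3,B:0);")
  m <- trait_model(0.6, 1.1, root_prior = "fixed_present")
  set.seed(8)
  ends <- vapply(1:4000, function(i)
    unclass(simulate_traits(two, m))[["A"]], character(1))
  p_emp <- mean(ends == "present")
  p_true <- transition_matrix(0.6, 1.1, 1.3)["present", "present"]
  expect_gt(stats::binom.test(sum(ends == "present"), 4000,
                              p_true)$p.value, 0.01)
  # seed reproducibility
  expect_identical(unclass(simulate_traits(two, m, seed = 9)),
                   unclass(simulate_traits(two, m, seed = 9)))
})

test_that("codon simulation emits no stops and respects omega = 0", {
  tr <- simulate_tree(12, delta_fraction = 0.4, total_length = 30, seed = 10)
  aln <- simulate_codon_alignment(tr, 20, omega_alpha = 0, omega_delta = 0,
                                  seed = 11)
  # the 61-state chain cannot visit stop codons
  stops <- c("TAA", "TAG", "TGA")
  for (s in aln$seqs) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(cods %in% stops))
  }
  # omega 0: every sequence translates identically
  aas <- vapply(aln$seqs, function(s)
    paste(paralogsel:::.codon_tables()$aa[
      match(substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)),
            sense_codons())], collapse = ""), character(1))
  expect_equal(length(unique(aas)), 1L)
  expect_identical(
    simulate_codon_alignment(tr, 5, seed = 12)$seqs,
    simulate_codon_alignment(tr, 5, seed = 12)$seqs)
})

test_that("trace simulation hits the requested SSI and decay constant", {
  tr0 <- simulate_trace(I_peak = -12, I_ss = -3, I_amil = -0.4,
                        noise_sd = 0)
  expect_equal(trace_ssi(tr0)$ssi, attr(tr0, "ssi_true"), tolerance = 1e-6)
  expect_equal(attr(tr0, "ssi_true"), (-12 + 3) / (-12 + 0.4))
  # fitted single exponential recovers tau within 10%
  trn <- simulate_trace(tau = 2.5, noise_sd = 0.02, seed = 13)
  sel <- trn$time > 10.2 & trn$time < 40
  fit <- stats::nls(I ~ a + b * exp(-(t - 10.1) / tau),
                    data = data.frame(t = trn$time[sel],
                                      I = trn$current[sel]),
                    start = list(a = -4, b = -6, tau = 1.5))
  expect_equal(coef(fit)[["tau"]], 2.5, tolerance = 0.1)
  expect_identical(simulate_trace(seed = 14)$current,
                   simulate_trace(seed = 14)$current)
})

test_that("count simulation carries recoverable truth labels", {
  # deterministic sampling with wide margins: calls recover truth exactly
  cs <- simulate_counts(400, expressed_fraction = 0.6,
                        sampling = "deterministic", seed = 15)
  calls <- expression_call(cs$counts, cs$lengths, cs$library_total,
                           gene_ids = cs$gene_ids)
  expect_equal(calls$expressed, cs$truth$expressed_true)
  # poisson sampling: called fraction close to the designed fraction
  cp <- simulate_counts(1000, expressed_fraction = 0.7, seed = 16)
  callp <- expression_call(cp$counts, cp$lengths, cp$library_total)
  expect_lt(abs(mean(callp$expressed) - 0.7), 0.03)
  # library-scaling invariance on the simulated table
  half <- expression_call(cp$counts * 2, cp$lengths, cp$library_total * 2)
  expect_equal(half$value, callp$value)
})
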