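test_that("detect_events recovers constructed currents exactly", {
  tr <- simulate_trace(I_baseline = -0.3, I_peak = -10, I_ss = -4,
                       I_amil = -0.5, noise_sd = 0)
  ev <- detect_events(tr)
  expect_equal(ev$I_peak, -10)
  expect_equal(ev$I_ss, -4, tolerance = 1e-6)
  expect_equal(ev$I_amil, -0.5, tolerance = 1e-6)
  # flat between switch and amiloride: no peak beyond the plateau -> SSI 0
  flat <- current_trace(seq(0, 100, 0.1),
                        c(rep(-5, 801), rep(-0.5, 200)),
                        t_switch = 10, t_amiloride = 80)
  evf <- detect_events(flat)
  expect_equal(evf$I_peak, evf$I_ss)
  expect_equal(compute_ssi(evf$I_peak, evf$I_ss, evf$I_amil)$ssi, 0)
})

test_that("trace construction and windows reject invalid annotations", {
  expect_error(current_trace(0:10, rep(-1, 11), t_switch = 8,
                             t_amiloride = 5), "before switch")
  expect_error(current_trace(c(0, 0, 1), rep(-1, 3), 0.1, 0.5),
               "strictly increasing")
  # steady-state window must not overlap amiloride
  tr <- current_trace(seq(0, 100, 0.1), rep(-1, 1001), t_switch = 10,
                      t_amiloride = 60)
  expect_error(detect_events(tr), "overlaps")
})

test_that("compute_ssi implements the amiloride-normalized fraction", {
  expect_equal(compute_ssi(-10, -10, -0.5)$ssi, 0)   # no decay
  expect_equal(compute_ssi(-10, -0.5, -0.5)$ssi, 1)  # decay to baseline
  expect_equal(compute_ssi(-10, -4, -0.5)$ssi, 6 / 9.5)
  r <- compute_ssi(-5, -5, -5)
  expect_true(r$undefined)
  expect_true(is.na(r$ssi))
  over <- compute_ssi(-10, -0.2, -0.5)
  expect_true(over$clamped)
  expect_equal(over$ssi, 1)
})

test_that("SSI is gain-invariant and monotone in the steady-state current", {
  set.seed(12)
  for (i in 1:10) {
    pk <- -runif(1, 5, 20)
    am <- runif(1, -1, 0)
    ssv <- seq(pk, am, length.out = 7)
    vals <- vapply(ssv, function(s) compute_ssi(pk, s, am)$ssi, numeric(1))
    expect_true(all(diff(vals) > 0))        # I_ss toward I_amil raises SSI
    k <- runif(1, 0.1, 10)                  # gain change leaves SSI alone
    expect_equal(compute_ssi(k * pk, k * ssv[3], k * am)$ssi, vals[3],
                 tolerance = 1e-12)
  }
})

test_that("group comparisons cover the t-test / ANOVA / Sidak cases", {
  gg <- rep(c("a", "b"), each = 3)
  # constant identical groups: zero pooled variance, flagged, p = 1
  same <- compare_groups(rep(5, 6), gg, "two-sample")
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)
  # identical but non-constant groups: ordinary t-test, p = 1
  idv <- c(1, 2, 3, 1, 2, 3)
  expect_equal(compare_groups(idv, gg, "two-sample")$p_value, 1)
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.01, 3), 1 - 0.99^3)
  # paired on identical data
  pp <- compare_groups(idv, gg, "paired")
  expect_equal(pp$statistic, 0)
  # standard two-sample agrees with stats::t.test
  x <- c(0.61, 0.65, 0.59, 0.66); y <- c(0.21, 0.18, 0.25, 0.22)
  r <- compare_groups(c(x, y), rep(c("wt", "mut"), each = 4), "two-sample")
  expect_equal(r$p_value,
               t.test(y, x, var.equal = TRUE)$p.value)
  # one-way with three groups returns Sidak-adjusted pairwise table
  v <- c(x, y, c(0.4, 0.44, 0.38, 0.41))
  g3 <- rep(c("a", "b", "c"), each = 4)
  ow <- compare_groups(v, g3, "one-way")
  expect_equal(nrow(ow$pairwise), 3)
  expect_true(all(ow$pairwise$p_sidak >= ow$pairwise$p_raw))
  expect_equal(ow$pairwise$p_sidak,
               sidak_adjust(ow$pairwise$p_raw, 3))
  expect_lt(ow$p_value, 0.001)
})

test_that("expression_call applies the RPKM formula and strict threshold", {
  ec <- expression_call(c(10, 0, 3), c(2000, 1000, 10000), 1e6)
  expect_equal(ec$value, c(5, 0, 0.3))
  expect_equal(ec$expressed, c(TRUE, FALSE, FALSE))  # 0.3 is background
  # scale consistency: doubling counts and library total changes nothing
  ec2 <- expression_call(c(20, 0, 6), c(2000, 1000, 10000), 2e6)
  expect_equal(ec2$value, ec$value)
  expect_error(expression_call(5, 0, 1e6), "length")
  expect_error(expression_call(5, 100, 0), "library")
  expect_error(expression_call(-1, 100, 1e6), "negative")
})

test_that("RPKM values match the edgeR reference implementation", {
  counts <- matrix(c(11, 0, 250, 7, 1200, 3), ncol = 1)
  lens <- c(500, 900, 1500, 2500, 4000, 10000)
  ours <- expression_call(counts[, 1], lens, sum(counts))$value
  dge <- edgeR::DGEList(counts = counts)
  ref <- edgeR::rpkm(dge, gene.length = lens, normalized.lib.sizes = FALSE)
  expect_equal(ours, ref[, 1], tolerance = 1e-9, ignore_attr = TRUE)
})
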