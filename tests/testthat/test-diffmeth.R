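test_that("Fisher p-values match hand-computed examples", {
  # 10/10 methylated vs 0/10: the two extreme tables of the margin
  expect_equal(fisher_test_counts(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_test_counts(8, 2, 2, 8), 0.023014, tolerance = 1e-4)
  expect_equal(fisher_test_counts(5, 5, 5, 5), 1)
  expect_error(fisher_test_counts(0, 0, 0, 0), "all-zero")
})

test_that("Fisher p-values equal exhaustive enumeration (margins <= 30)", {
  # exhaustive over all tables with both row sums <= 8
  for (r1 in 1:8) for (r2 in 1:8) for (a in 0:r1) for (cc in 0:r2) {
    p <- fisher_test_counts(a, r1 - a, cc, r2 - cc)
    expect_equal(p, fisher_oracle(a, r1 - a, cc, r2 - cc),
                 tolerance = 1e-12)
  }
  # random tables with margins up to 30
  set.seed(77)
  for (i in 1:200) {
    r1 <- sample(1:30, 1); r2 <- sample(1:30, 1)
    a <- sample(0:r1, 1); cc <- sample(0:r2, 1)
    expect_equal(fisher_test_counts(a, r1 - a, cc, r2 - cc),
                 fisher_oracle(a, r1 - a, cc, r2 - cc), tolerance = 1e-12)
  }
})

test_that("Fisher p-values agree with stats::fisher.test", {
  set.seed(5)
  a <- rbinom(100, 40, 0.4); b <- 40 - a
  cc <- rbinom(100, 35, 0.6); d <- 35 - cc
  ours <- fisher_test_counts(a, b, cc, d)
  ref <- vapply(1:100, function(i)
    stats::fisher.test(matrix(c(a[i], b[i], cc[i], d[i]), 2,
                              byrow = TRUE))$p.value, numeric(1))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_adjust(c(0.001, 0.008, 0.039, 0.041)),
               c(0.004, 0.016, 0.041, 0.041))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  # permutation invariance of the p -> q mapping
  p <- c(0.3, 0.001, 0.07, 0.001, 0.9)
  o <- c(4, 2, 5, 1, 3)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DmC calling labels directions and respects the FDR threshold", {
  depth <- matrix(100, 3, 3)
  mset <- make_mset(
    list(flight = depth, ground = depth),
    meths = list(flight = rbind(rep(80, 3), rep(10, 3), rep(50, 3)),
                 ground = rbind(rep(30, 3), rep(60, 3), rep(50, 3))))
  tbl <- call_dmcs(dmc_test(mset, rep(TRUE, 3)), fdr = 0.01)
  expect_equal(tbl$diff, c(0.5, -0.5, 0), tolerance = 1e-12)
  expect_equal(tbl$is_dmc, c(TRUE, TRUE, FALSE))
  expect_equal(tbl$direction[1:2], c("hyper", "hypo"))
})

test_that("an all-null site panel yields essentially no DmC calls", {
  b <- simulate_dmc_benchmark(n_sites = 5000, signal_fraction = 0,
                              depth = 50, seed = 13)
  tbl <- call_dmcs(dmc_test(b$mset, coverage_gate(b$mset)), fdr = 0.01)
  expect_lte(sum(tbl$is_dmc), 2)
})

test_that("DMR windows require 4 DmCs, 0.2 difference and significance", {
  tbl <- dmc_fixture_table(
    window_sites("Chr1", 0, n_dmc = 5, diff = 0.3),      # qualifies
    window_sites("Chr1", 500, n_dmc = 3, diff = 0.5),    # only 3 DmCs
    window_sites("Chr1", 900, n_dmc = 6, n_null = 24, diff = 0.5))
  # third window: 6 strong DmCs but pooled diff 6*0.5/30 = 0.1 < 0.2
  dmrs <- call_dmrs(tbl)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, 0)
  expect_equal(dmrs$end, 100)
  expect_equal(dmrs$direction, "hyper")
  expect_gte(dmrs$n_dmcs, 4)
})

test_that("qualifying windows separated by one window merge, by two do not", {
  joined <- call_dmrs(dmc_fixture_table(
    window_sites("Chr1", 0, n_dmc = 5, diff = 0.3),
    window_sites("Chr1", 200, n_dmc = 5, diff = 0.3)))
  expect_equal(nrow(joined), 1)
  expect_equal(c(joined$start, joined$end), c(0, 300))
  expect_equal(joined$n_windows_merged, 2)
  expect_equal(joined$n_dmcs, 10)

  apart <- call_dmrs(dmc_fixture_table(
    window_sites("Chr1", 0, n_dmc = 5, diff = 0.3),
    window_sites("Chr1", 300, n_dmc = 5, diff = 0.3)))
  expect_equal(nrow(apart), 2)

  opposite <- call_dmrs(dmc_fixture_table(
    window_sites("Chr1", 0, n_dmc = 5, diff = 0.3),
    window_sites("Chr1", 200, n_dmc = 5, diff = -0.3)))
  expect_equal(nrow(opposite), 2)
  expect_true(all(opposite$n_windows_merged == 1))
})

test_that("no two reported DMRs of one direction are within one window", {
  set.seed(2)
  parts <- lapply(seq(0, 4000, by = 100), function(s)
    window_sites("Chr1", s, n_dmc = sample(0:6, 1), n_null = 2,
                 diff = 0.4))
  dmrs <- call_dmrs(do.call(dmc_fixture_table, parts))
  if (nrow(dmrs) > 1) {
    d <- dmrs[order(dmrs$start), ]
    same <- d$direction[-1] == d$direction[-nrow(d)]
    gaps <- d$start[-1] - d$end[-nrow(d)]
    expect_true(all(gaps[same] > 100))
  }
  # idempotence of the gating: every reported DMR satisfies the gates
  expect_true(all(dmrs$n_dmcs >= 4))
  expect_true(all(abs(dmrs$mean_diff) >= 0.2))
  expect_true(all(dmrs$q_value < 0.01))
})

test_that("differential summaries partition by direction and context", {
  tbl <- dmc_fixture_table(
    window_sites("Chr1", 0, n_dmc = 5, diff = 0.3, context = "CHH"),
    window_sites("Chr1", 1000, n_dmc = 3, diff = -0.4, context = "CHH"),
    window_sites("Chr1", 2000, n_dmc = 2, diff = 0.5, context = "CG"))
  dmrs <- call_dmrs(tbl)
  s <- summarize_differential(tbl, dmrs)
  expect_equal(unname(s$dmc_counts["CHH", "total"]),
               unname(sum(s$dmc_counts["CHH", c("hyper", "hypo")])))
  expect_equal(unname(s$dmc_counts["CHH", c("hyper", "hypo")]), c(5L, 3L))
  expect_equal(unname(s$dmc_counts["CG", "hyper"]), 2L)
  # the only DMR is the first CHH window; its 5 DmCs lie inside it
  expect_equal(unname(s$dmcs_in_dmrs["CHH"]), 5L)
  expect_lte(sum(s$dmcs_in_dmrs), sum(s$dmc_counts[, "total"]))
})
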