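make_eset <- function(counts, lengths = NULL,
                      conds = rep(c("flight", "ground"), each = ncol(counts) / 2)) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  samples <- data.frame(sample_id = paste0("s", seq_len(ncol(counts))),
                        condition = conds, organ = "root",
                        replicate = ave(seq_len(ncol(counts)), conds,
                                        FUN = seq_along))
  if (is.null(lengths))
    lengths <- stats::setNames(rep(1000, nrow(counts)), rownames(counts))
  expression_set(counts, samples, lengths)
}

test_that("CPM and FPKM follow their definitions", {
  counts <- matrix(c(500, 999500, 0, 1e6 - 0), 2, 2)
  counts[2, 2] <- 1e6
  es <- make_eset(counts, lengths = c(g1 = 1000, g2 = 2000),
                  conds = c("flight", "ground"))
  cf <- cpm_fpkm(es)
  expect_equal(cf$cpm["g1", 1], 500)
  expect_equal(cf$fpkm["g1", 1], 500)
  expect_equal(cf$cpm["g1", 2], 0)
  expect_equal(cf$fpkm["g2", 1], 999500 / 2)
})

test_that("CPM is invariant to scaling a sample's counts", {
  set.seed(1)
  counts <- matrix(rpois(60, 50), 10)
  es1 <- make_eset(counts)
  counts2 <- counts; counts2[, 3] <- counts2[, 3] * 7L
  es2 <- make_eset(counts2)
  expect_equal(cpm_fpkm(es1)$cpm[, 3], cpm_fpkm(es2)$cpm[, 3])
})

test_that("the CPM gate requires CPM strictly above 5 in 3 samples", {
  lib <- 1e6
  counts <- rbind(c(6, 6, 6, 0, 0, 0),
                  c(6, 6, 0, 0, 0, 0),
                  c(5, 5, 5, 5, 5, 5)) # CPM exactly 5 everywhere
  # pad each library to exactly 1e6 reads so counts are CPM
  cnt <- rbind(counts, lib - colSums(counts))
  es <- make_eset(cnt)
  keep <- expression_gate(es, min_cpm = 5, min_samples = 3)
  expect_true(keep[1])
  expect_false(keep[2])
  expect_false(keep[3])
})

test_that("the expression gate is monotone in min_cpm", {
  set.seed(2)
  es <- make_eset(matrix(rnbinom(600, mu = 30, size = 5), 100))
  expect_true(all(expression_gate(es, 10, 3) <= expression_gate(es, 5, 3)))
})

test_that("TMM factors are 1 for identical or purely scaled libraries", {
  counts <- matrix(rpois(200, 100), 100, 2)
  counts[, 2] <- counts[, 1]
  expect_equal(normalize_tmm(counts), c(1, 1))
  counts[, 2] <- counts[, 1] * 2L
  f <- normalize_tmm(counts)
  expect_equal(f[1], f[2], tolerance = 1e-12)
  expect_equal(prod(f), 1, tolerance = 1e-12)
  # invariance to gene order
  perm <- sample(nrow(counts))
  expect_equal(normalize_tmm(counts[perm, ]), f)
})

test_that("NB test p-values are near-uniform under the null", {
  genes <- gene_models(sprintf("G%04d", 1:5000), "Chr1", (0:4999) * 10,
                       (0:4999) * 10 + 5, rep("+", 5000))
  cfg <- sim_config(seed = 14, n_true_degs = 0, nb_dispersion = 0.1)
  se <- simulate_expression(genes, cfg)
  res <- nb_test(se$eset)
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("NB test recovers planted fold-changes and is antisymmetric", {
  genes <- gene_models(sprintf("G%04d", 1:600), "Chr1", (0:599) * 10,
                       (0:599) * 10 + 5, rep("+", 600))
  cfg <- sim_config(seed = 15, n_true_degs = 200, deg_log2fc = 2,
                    nb_dispersion = 0.1, expr_mean_log = log(500),
                    expr_sd_log = 0, coupling_fraction = 0)
  se <- simulate_expression(genes, cfg)
  res <- nb_test(se$eset)
  planted <- names(se$truth$deg_log2fc)
  est <- abs(res$log2fc[match(planted, res$gene_id)])
  expect_lt(abs(median(est) - 2), 0.2)

  swapped <- nb_test(se$eset, test = "ground", control = "flight")
  expect_equal(swapped$log2fc, -res$log2fc, tolerance = 1e-8)
})

test_that("NB test agrees with an independent exact NB test on rankings", {
  genes <- gene_models(sprintf("G%04d", 1:800), "Chr1", (0:799) * 10,
                       (0:799) * 10 + 5, rep("+", 800))
  cfg <- sim_config(seed = 16, n_true_degs = 100, deg_log2fc = 1.5,
                    nb_dispersion = 0.15)
  se <- simulate_expression(genes, cfg)
  keep <- expression_gate(se$eset)
  es <- expression_set(se$eset$counts[keep, ], se$eset$samples,
                       se$eset$gene_lengths[keep])
  res <- nb_test(es)

  dge <- edgeR::DGEList(es$counts,
                        group = factor(es$samples$condition,
                                       levels = c("ground", "flight")))
  dge <- edgeR::calcNormFactors(dge)
  dge <- edgeR::estimateDisp(dge)
  et <- edgeR::exactTest(dge)
  expect_gt(cor(res$log2fc, et$table$logFC), 0.98)
  expect_gt(cor(rank(res$p_value), rank(et$table$PValue)), 0.9)
})

test_that("DEG calls enforce the FDR, fold-change and FPKM thresholds", {
  set.seed(3)
  counts <- matrix(rpois(60, 1000), 10)
  es <- make_eset(counts)
  res <- data.frame(gene_id = rownames(es$counts),
                    log2fc = c(1.5, 0.8, -1.2, rep(0, 7)),
                    p_value = c(1e-5, 1e-5, 1e-5, rep(0.9, 7)))
  degs <- call_degs(res, es, fdr = 0.05, min_fold = 2)
  expect_true(degs$is_deg[1])
  expect_false(degs$is_deg[2])   # fold change below 2
  expect_true(degs$is_deg[3])    # downregulation counts too
  expect_false(any(degs$is_deg[4:10]))
  expect_true(all(abs(degs$log2fc[degs$is_deg]) >= 1))
})

test_that("organ Venn counts follow set arithmetic", {
  v <- deg_venn(c("a", "b", "c"), c("b", "c", "d", "e"))
  expect_equal(unname(v), c(3L, 4L, 2L, 5L))
  expect_equal(unname(v["union"]),
               unname(v["n_a"] + v["n_b"] - v["shared"]))
})

test_that("expression tables round-trip through TSV", {
  set.seed(4)
  es <- make_eset(matrix(rpois(60, 100), 10))
  dir <- tempfile()
  paths <- write_expression_tables(es, dir)
  back <- read_expression_tables(paths["counts"], paths["samples"],
                                 paths["lengths"])
  expect_equal(back$counts, es$counts)
  expect_equal(back$gene_lengths, es$gene_lengths)
})
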