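test_that("features map to upstream, body and downstream strand-aware", {
  genes <- gene_models("g1", "Chr1", 1000, 2000, "+")
  feats <- data.frame(chrom = "Chr1", pos = c(500, 1500, 2500, 5000))
  a <- assign_region(feats, genes, flank = 2000)
  expect_equal(a$pos, c(500, 1500, 2500))
  expect_equal(a$region, c("upstream", "body", "downstream"))

  minus <- gene_models("g2", "Chr1", 1000, 2000, "-")
  am <- assign_region(data.frame(chrom = "Chr1", pos = c(2500, 500)), minus)
  expect_equal(am$region[am$pos == 2500], "upstream")
  expect_equal(am$region[am$pos == 500], "downstream")
})

test_that("interval features and overlapping genes get every assignment", {
  genes <- gene_models(c("a", "b"), "Chr1", c(1000, 1500), c(2000, 2600),
                       c("+", "+"))
  dmr <- data.frame(chrom = "Chr1", start = 1900, end = 1960)
  a <- assign_region(dmr, genes)
  expect_setequal(paste(a$gene_id, a$region),
                  c("a body", "b body"))
})

test_that("flanks truncate at chromosome ends", {
  genes <- gene_models("g1", "Chr1", 500, 1500, "+")
  a <- assign_region(data.frame(chrom = "Chr1", pos = 100), genes,
                     flank = 2000, seqlens = c(Chr1 = 1600))
  expect_equal(a$region, "upstream")
  # downstream flank would extend past the end; position beyond it is gone
  a2 <- assign_region(data.frame(chrom = "Chr1", pos = 1590), genes,
                      flank = 2000, seqlens = c(Chr1 = 1600))
  expect_equal(a2$region, "downstream")
})

test_that("region intervals of an isolated gene tile its neighborhood", {
  genes <- gene_models("g", "Chr1", 5000, 7000, "-")
  pos <- 3000:8999
  a <- assign_region(data.frame(chrom = "Chr1", pos = pos), genes)
  expect_equal(nrow(a), length(pos))          # every position in one region
  expect_equal(anyDuplicated(a$pos), 0)       # and only one
  expect_equal(sum(a$region == "body"), 2000)
  expect_equal(sum(a$region == "upstream"), 2000)
  expect_equal(sum(a$region == "downstream"), 2000)
})

test_that("genes_affected de-duplicates features per gene and cell", {
  asg <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2", "g2"),
    region = c("body", "body", "body", "body", "body"),
    context = c("CG", "CG", "CG", "CHH", "CHH"),
    direction = c("hyper", "hyper", "hyper", "hyper", "hypo"))
  ga <- genes_affected(asg)
  expect_equal(ga$n_genes[ga$region == "body" & ga$context == "CG" &
                          ga$direction == "hyper"], 1L)
  expect_equal(ga$n_genes[ga$region == "body" & ga$context == "CHH" &
                          ga$direction == "hyper"], 1L)
  expect_equal(ga$n_genes[ga$region == "body" & ga$context == "CHH" &
                          ga$direction == "hypo"], 1L)
  expect_equal(sum(genes_affected(asg[0, ])$n_genes), 0L)
})

test_that("genes_affected equals a brute-force set comprehension", {
  set.seed(10)
  genes <- gene_models(paste0("g", 1:20), "Chr1", (0:19) * 5000,
                       (0:19) * 5000 + 2000,
                       sample(c("+", "-"), 20, replace = TRUE))
  feats <- data.frame(chrom = "Chr1",
                      pos = sample(0:99999, 300),
                      context = sample(c("CG", "CHG", "CHH"), 300, TRUE),
                      direction = sample(c("hyper", "hypo"), 300, TRUE))
  a <- assign_region(feats, genes)
  ga <- genes_affected(a)
  for (i in sample(nrow(ga), 10)) {
    ids <- unique(a$gene_id[a$region == ga$region[i] &
                            a$context == ga$context[i] &
                            a$direction == ga$direction[i]])
    expect_equal(ga$n_genes[i], length(ids))
  }
})

test_that("metagene profile is flat for uniform methylation", {
  genes <- gene_models(c("g1", "g2"), "Chr1", c(3000, 9000), c(5000, 10500),
                       c("+", "-"))
  lv <- data.frame(chrom = "Chr1", pos = seq(0, 12999, by = 7),
                   context = "CG", level = 0.3)
  pr <- metagene_profile(lv, genes)
  expect_true(all(abs(pr$mean_level - 0.3) < 1e-12))
  expect_equal(sort(unique(pr$segment)),
               c("body", "downstream", "upstream"))
})

test_that("metagene profile reproduces a planted flank-vs-body step", {
  genes <- gene_models("g1", "Chr1", 4000, 6000, "+")
  pos <- seq(0, 9999, by = 3)
  lv <- data.frame(chrom = "Chr1", pos = pos, context = "CHH",
                   level = ifelse(pos >= 4000 & pos < 6000, 0.05, 0.2))
  pr <- metagene_profile(lv, genes)
  up <- pr$mean_level[pr$segment == "upstream"]
  body <- pr$mean_level[pr$segment == "body"]
  expect_true(all(abs(up - 0.2) < 1e-12))
  expect_true(all(abs(body - 0.05) < 1e-12))
})

test_that("minus-strand genes contribute their genomic right flank upstream", {
  genes <- gene_models("g1", "Chr1", 4000, 6000, "-")
  pos <- seq(0, 9999, by = 3)
  lv <- data.frame(chrom = "Chr1", pos = pos, context = "CG",
                   level = ifelse(pos < 4000, 0.1,
                                  ifelse(pos < 6000, 0.3, 0.7)))
  pr <- metagene_profile(lv, genes)
  expect_true(all(abs(pr$mean_level[pr$segment == "upstream"] - 0.7) < 1e-12))
  expect_true(all(abs(pr$mean_level[pr$segment == "downstream"] - 0.1) < 1e-12))
})

test_that("profiles are invariant under reverse-complementing the genome", {
  set.seed(6)
  n <- 20000
  seq <- random_genome_seq(n)
  g <- genome(c(Chr = seq), chloroplast = "Chr")
  sites <- enumerate_cytosine_sites(g)
  sites$level <- runif(nrow(sites))
  genes <- gene_models(c("a", "b"), "Chr", c(3000, 12000), c(5500, 15000),
                       c("+", "-"))
  pr <- metagene_profile(sites, genes)

  m_sites <- sites
  m_sites$pos <- n - 1L - sites$pos   # mirrored coordinates, levels carried
  m_genes <- gene_models(genes$gene_id, "Chr", n - genes$end,
                         n - genes$start,
                         ifelse(genes$strand == "+", "-", "+"))
  pr_m <- metagene_profile(m_sites, m_genes)
  expect_equal(pr, pr_m)
})

test_that("short genes are excluded from metagene profiles", {
  genes <- gene_models("tiny", "Chr1", 100, 150, "+")
  lv <- data.frame(chrom = "Chr1", pos = 0:299, context = "CG", level = 0.5)
  expect_equal(nrow(metagene_profile(lv, genes, body_bins = 100)), 0)
})

test_that("gene models round-trip through BED and parse from GFF3", {
  genes <- gene_models(c("AT1", "AT2"), c("Chr1", "Chr2"), c(100, 900),
                       c(600, 2400), c("+", "-"))
  f <- tempfile(fileext = ".bed")
  write_gene_bed(genes, f)
  expect_equal(read_gene_models(f), genes)

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "Chr1\tsrc\tgene\t101\t600\t.\t+\t.\tID=AT1;Name=x",
               "Chr1\tsrc\tmRNA\t101\t600\t.\t+\t.\tID=AT1.1",
               "Chr2\tsrc\tgene\t901\t2400\t.\t-\t.\tID=AT2"), gff)
  expect_equal(read_gene_models(gff), genes)
})
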