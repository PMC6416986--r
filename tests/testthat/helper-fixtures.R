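# Small in-code fixtures shared across test files.

# A methylome_set over explicit per-replicate total (and optionally
# methylated) counts. `totals` is a list: condition -> matrix sites x reps.
make_mset <- function(totals, meths = NULL, contexts = "CG",
                      chloroplast = NA_character_, chrom = "Chr1") {
  conds <- names(totals)
  total <- do.call(cbind, totals)
  meth <- if (is.null(meths)) matrix(0L, nrow(total), ncol(total))
          else do.call(cbind, meths)
  n_rep <- vapply(totals, ncol, integer(1))
  samples <- data.frame(
    sample_id = paste0(rep(conds, n_rep), "_", unlist(lapply(n_rep, seq_len))),
    condition = rep(conds, n_rep), organ = "root",
    replicate = unlist(lapply(n_rep, seq_len)), stringsAsFactors = FALSE)
  sites <- data.frame(chrom = chrom, pos = (seq_len(nrow(total)) - 1L) * 10L,
                      strand = "+",
                      context = rep_len(contexts, nrow(total)),
                      stringsAsFactors = FALSE)
  methylome_set(sites, samples, meth, total, chloroplast = chloroplast)
}

# Pooled-count site rows for one 100 bp DMR window: n_dmc strong sites
# (control level 0.5, test level 0.5 + diff) and n_null equal-level sites.
window_sites <- function(chrom, wstart, n_dmc, n_null = 0, diff = 0.5,
                         depth = 200, context = "CG") {
  n <- n_dmc + n_null
  stopifnot(n <= 100, abs(diff) <= 0.5)
  mc <- round(0.5 * depth)
  mt <- c(rep(round((0.5 + diff) * depth), n_dmc), rep(mc, n_null))
  data.frame(chrom = chrom, pos = wstart + seq_len(n) - 1L, strand = "+",
             context = context,
             meth_test = mt, total_test = depth,
             meth_control = mc, total_control = depth,
             stringsAsFactors = FALSE)
}

# Assemble window fixtures into a DmC-called site table ready for
# call_dmrs(): p-values from the package's Fisher test, BH + direction
# from call_dmcs().
dmc_fixture_table <- function(...) {
  tbl <- do.call(rbind, list(...))
  tbl$level_test <- tbl$meth_test / tbl$total_test
  tbl$level_control <- tbl$meth_control / tbl$total_control
  tbl$diff <- tbl$level_test - tbl$level_control
  tbl$p_value <- fisher_test_counts(
    tbl$meth_test, tbl$total_test - tbl$meth_test,
    tbl$meth_control, tbl$total_control - tbl$meth_control)
  call_dmcs(tbl, fdr = 0.01)
}

# Exhaustive hypergeometric enumeration oracle for the two-sided Fisher
# test on [[a, b], [c, d]], written from choose() only.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- vapply(support, prob, numeric(1))
  sum(probs[probs <= prob(a) * (1 + 1e-7)])
}

# Regex oracle for cytosine contexts: forward patterns on the sequence
# and on its reverse complement (lookahead so overlapping sites count).
regex_context_sites <- function(seq) {
  pats <- c(CG = "C(?=G)", CHG = "C(?=[ACT]G)", CHH = "C(?=[ACT][ACT])")
  hit <- function(s, pat) {
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  n <- nchar(seq)
  rc <- methexpress::reverse_complement(seq)
  fwd <- do.call(rbind, lapply(names(pats), function(cc) {
    p <- hit(seq, pats[[cc]])
    data.frame(pos = p, strand = rep("+", length(p)), context = cc)
  }))
  rev <- do.call(rbind, lapply(names(pats), function(cc) {
    p <- hit(rc, pats[[cc]])
    data.frame(pos = n - 1L - p, strand = rep("-", length(p)), context = cc)
  }))
  out <- rbind(fwd, rev)
  out[order(out$pos, out$strand), ]
}

random_genome_seq <- function(n, with_n = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}
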