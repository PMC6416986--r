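#' Vectorized two-sided Fisher exact test for 2x2 count tables
#'
#' For tables `[[a, b], [c, d]]` (here: methylated/unmethylated in test and
#' control), the two-sided p-value is the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (minimum-likelihood method,
#' as in `stats::fisher.test`).
#'
#' @param a,b,c,d Non-negative integer vectors (recycled to common length).
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
fisher_test_counts <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("counts must be non-negative")
  if (any(a + b + c + d == 0)) stop("all-zero 2x2 table")
  rel_tol <- 1 + 1e-7   # guards against ties lost to floating point
  vapply(seq_len(n), function(i) {
    white <- a[i] + c[i]           # methylated margin
    black <- b[i] + d[i]           # unmethylated margin
    k <- a[i] + b[i]               # test-condition margin
    lo <- max(0, k - black); hi <- min(k, white)
    dens <- stats::dhyper(lo:hi, white, black, k)
    p <- sum(dens[dens <= dens[a[i] - lo + 1] * rel_tol])
    min(p, 1)
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (monotone enforced).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Site-level differential methylation tests
#'
#' Replicate counts are pooled within each condition and each gated site is
#' tested with a two-sided Fisher exact test on the 2x2 table of pooled
#' methylated / unmethylated counts. The effect size is the difference of
#' pooled levels, test minus control (positive = hypermethylated in the
#' test condition).
#'
#' @param mset A [methylome_set()] with two conditions.
#' @param gate Logical site vector from [coverage_gate()] (or any subset).
#' @param test,control Condition labels (defaults `"flight"`, `"ground"`).
#' @return data.frame of gated sites with pooled counts per condition
#'   (`meth_test`, `total_test`, `meth_control`, `total_control`), levels,
#'   `diff` and `p_value`.
#' @export
dmc_test <- function(mset, gate, test = "flight", control = "ground") {
  ft <- pooled_levels(mset, test, which = gate)
  gr <- pooled_levels(mset, control, which = gate)
  out <- ft[, c("chrom", "pos", "strand", "context")]
  out$meth_test <- ft$meth;    out$total_test <- ft$total
  out$meth_control <- gr$meth; out$total_control <- gr$total
  out$level_test <- ft$level;  out$level_control <- gr$level
  out$diff <- ft$level - gr$level
  out$p_value <- fisher_test_counts(
    ft$meth, ft$total - ft$meth, gr$meth, gr$total - gr$meth)
  out
}

#' Call differentially methylated cytosines (DmCs)
#'
#' q-values are computed by Benjamini-Hochberg over all tested sites of the
#' organ, all contexts jointly; a DmC is a site with `q < fdr`, labelled
#' hyper (level higher in the test condition) or hypo.
#'
#' @param tbl Site table from [dmc_test()].
#' @param fdr FDR threshold (default 0.01).
#' @return `tbl` with added `q_value`, `direction` and logical `is_dmc`.
#' @export
call_dmcs <- function(tbl, fdr = 0.01) {
  tbl$q_value <- bh_adjust(tbl$p_value)
  tbl$direction <- ifelse(tbl$diff > 0, "hyper",
                          ifelse(tbl$diff < 0, "hypo", NA_character_))
  tbl$is_dmc <- tbl$q_value < fdr & !is.na(tbl$direction)
  tbl
}

#' Call differentially methylated regions (DMRs)
#'
#' Chromosomes are tiled per context with fixed, non-overlapping windows
#' anchored at position 0. A window qualifies when it contains at least
#' `min_dmcs` DmCs, its pooled-count level difference between conditions
#' is at least `min_diff` in absolute value, and a Fisher exact test on
#' the window-pooled counts is significant below `alpha` after
#' Benjamini-Hochberg adjustment across all windows of the context.
#' Qualifying windows of the same direction separated by at most one
#' window are joined into a larger DMR; joined records re-aggregate
#' `n_dmcs` and `mean_diff` over their member windows.
#'
#' @param tbl DmC site table from [call_dmcs()].
#' @param window Window width in bp (default 100).
#' @param min_dmcs Minimum DmCs per window (default 4).
#' @param min_diff Minimum absolute pooled level difference (default 0.2).
#' @param alpha Window-level significance threshold (default 0.01).
#' @return data.frame of DMRs: `chrom, start, end, context, n_dmcs,
#'   mean_diff, q_value, direction, n_windows_merged` (0-based half-open
#'   coordinates).
#' @export
call_dmrs <- function(tbl, window = 100, min_dmcs = 4, min_diff = 0.2,
                      alpha = 0.01) {
  if (min_dmcs < 1) stop("min_dmcs must be at least 1")
  if (window <= 0) stop("window must be positive")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      n_dmcs = integer(), mean_diff = numeric(),
                      q_value = numeric(), direction = character(),
                      n_windows_merged = integer(), stringsAsFactors = FALSE)
  tbl <- tbl[tbl$context != "UNKNOWN", ]
  if (nrow(tbl) == 0) return(empty)
  res <- list()
  for (ctx in unique(tbl$context)) {
    d <- tbl[tbl$context == ctx, ]
    win <- d$pos %/% window
    key <- paste(d$chrom, win, sep = "\r")
    uk <- sort(unique(key))
    w <- data.frame(key = uk, stringsAsFactors = FALSE)
    sums <- lapply(list(n_dmcs = as.numeric(d$is_dmc),
                        mt = d$meth_test, tt = d$total_test,
                        mc = d$meth_control, tc = d$total_control),
                   function(x) tapply(x, key, sum)[uk])
    parts <- strsplit(uk, "\r", fixed = TRUE)
    w$chrom <- vapply(parts, `[`, character(1), 1L)
    w$win <- as.numeric(vapply(parts, `[`, character(1), 2L))
    w$n_dmcs <- as.integer(sums$n_dmcs)
    w$mt <- as.numeric(sums$mt); w$tt <- as.numeric(sums$tt)
    w$mc <- as.numeric(sums$mc); w$tc <- as.numeric(sums$tc)
    w$mean_diff <- w$mt / w$tt - w$mc / w$tc
    w$p <- fisher_test_counts(w$mt, w$tt - w$mt, w$mc, w$tc - w$mc)
    w$q <- bh_adjust(w$p)
    # small tolerance so exact-boundary differences are not lost to
    # floating-point rounding
    w$ok <- w$n_dmcs >= min_dmcs &
      abs(w$mean_diff) >= min_diff - 1e-9 &
      w$q < alpha & is.finite(w$mean_diff)
    q <- w[w$ok, ]
    if (nrow(q) == 0) next
    q <- q[order(q$chrom, q$win), ]
    q$dirsign <- sign(q$mean_diff)
    newrun <- c(TRUE, !(q$chrom[-1] == q$chrom[-nrow(q)] &
                        q$win[-1] - q$win[-nrow(q)] <= 2 &
                        q$dirsign[-1] == q$dirsign[-nrow(q)]))
    q$run <- cumsum(newrun)
    merged <- lapply(split(q, q$run), function(r) {
      md <- sum(r$mt) / sum(r$tt) - sum(r$mc) / sum(r$tc)
      data.frame(chrom = r$chrom[1],
                 start = as.integer(min(r$win) * window),
                 end = as.integer((max(r$win) + 1) * window),
                 context = ctx,
                 n_dmcs = sum(r$n_dmcs),
                 mean_diff = md,
                 q_value = min(r$q),
                 direction = if (md > 0) "hyper" else "hypo",
                 n_windows_merged = nrow(r), stringsAsFactors = FALSE)
    })
    res[[ctx]] <- do.call(rbind, merged)
  }
  if (length(res) == 0) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$context), ]
  rownames(out) <- NULL
  out
}

#' Summarize DmCs and DMRs per context and direction
#'
#' @param tbl DmC table from [call_dmcs()].
#' @param dmrs DMR table from [call_dmrs()].
#' @return List with `dmc_counts` and `dmr_counts` (context x direction)
#'   and `dmcs_in_dmrs` (per-context count of DmCs lying inside a
#'   same-context DMR).
#' @export
summarize_differential <- function(tbl, dmrs) {
  ctxs <- c("CG", "CHG", "CHH")
  count_tab <- function(d) {
    m <- matrix(0L, length(ctxs), 3,
                dimnames = list(ctxs, c("hyper", "hypo", "total")))
    if (nrow(d)) for (cc in ctxs) {
      m[cc, "hyper"] <- sum(d$context == cc & d$direction == "hyper")
      m[cc, "hypo"] <- sum(d$context == cc & d$direction == "hypo")
    }
    m[, "total"] <- m[, "hyper"] + m[, "hypo"]
    m
  }
  dmcs <- tbl[tbl$is_dmc, ]
  in_dmr <- stats::setNames(integer(length(ctxs)), ctxs)
  for (cc in ctxs) {
    dd <- dmcs[dmcs$context == cc, ]
    rr <- dmrs[dmrs$context == cc, ]
    if (nrow(dd) && nrow(rr)) {
      hit <- vapply(seq_len(nrow(dd)), function(i)
        any(rr$chrom == dd$chrom[i] & rr$start <= dd$pos[i] &
            dd$pos[i] < rr$end), logical(1))
      in_dmr[cc] <- sum(hit)
    }
  }
  list(dmc_counts = count_tab(dmcs), dmr_counts = count_tab(dmrs),
       dmcs_in_dmrs = in_dmr)
}

#' Write a DmC table as TSV
#' @param tbl Table from [call_dmcs()] (1-based positions on output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmc_table <- function(tbl, path) {
  out <- tbl
  out$pos <- out$pos + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write DMRs as BED6+3
#'
#' Columns: chrom, start, end, name (context), score (-log10 q, capped at
#' 1000), strand ("."), then n_dmcs, mean_diff, direction.
#'
#' @param dmrs Table from [call_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  score <- pmin(round(-log10(pmax(dmrs$q_value, 1e-300)), 2), 1000)
  out <- data.frame(dmrs$chrom, dmrs$start, dmrs$end, dmrs$context, score,
                    ".", dmrs$n_dmcs, round(dmrs$mean_diff, 4),
                    dmrs$direction)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
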