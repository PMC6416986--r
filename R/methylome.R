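#' Construct a methylome set
#'
#' The central container for per-cytosine bisulfite counts across samples:
#' a site table plus parallel methylated / total read-count matrices
#' (sites x samples), with per-sample metadata.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, one row per cytosine site.
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (e.g. `"flight"` / `"ground"`), `organ`, `replicate`.
#' @param meth,total Integer matrices, `nrow(sites)` x `nrow(samples)`,
#'   methylated and total read counts; `0 <= meth <= total` everywhere.
#' @param chloroplast Name of the chromosome used as unmethylated control,
#'   or `NA` if none present.
#' @return An object of class `"methylome_set"`.
#' @export
methylome_set <- function(sites, samples, meth, total, chloroplast = NA_character_) {
  stopifnot(nrow(meth) == nrow(sites), nrow(total) == nrow(sites),
            ncol(meth) == nrow(samples), ncol(total) == nrow(samples))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  meth <- as.matrix(meth); total <- as.matrix(total)
  if (any(meth < 0) || any(total < 0) || any(meth > total))
    stop("counts must satisfy 0 <= methylated <= total")
  colnames(meth) <- colnames(total) <- samples$sample_id
  structure(list(sites = sites, samples = samples, meth = meth,
                 total = total, chloroplast = chloroplast),
            class = "methylome_set")
}

#' @export
print.methylome_set <- function(x, ...) {
  cat("methylome_set:", nrow(x$sites), "sites x", nrow(x$samples),
      "samples (conditions:",
      paste(unique(x$samples$condition), collapse = "/"), ")\n")
  invisible(x)
}

#' Per-site methylation level
#'
#' The methylation level of a cytosine is the methylated read count divided
#' by the total read count. Sites with zero coverage have no defined level
#' and are returned as `NA`, never as 0.
#'
#' @param methylated,total Non-negative integer vectors.
#' @return Numeric vector of levels in \[0, 1\], `NA` where `total == 0`.
#' @export
site_level <- function(methylated, total) {
  if (any(methylated > total)) stop("methylated exceeds total")
  ifelse(total > 0, methylated / total, NA_real_)
}

#' Replicate-aware coverage gate
#'
#' A site enters the differential analysis only if, in each condition, at
#' least `min_reps` replicates cover it with at least `min_cov` reads.
#'
#' @param mset A [methylome_set()].
#' @param min_cov Minimum read coverage per replicate (default 10).
#' @param min_reps Minimum number of qualifying replicates per condition
#'   (default 2).
#' @return Logical vector over sites: `TRUE` for retained sites.
#' @export
coverage_gate <- function(mset, min_cov = 10, min_reps = 2) {
  conds <- unique(mset$samples$condition)
  keep <- rep(TRUE, nrow(mset$sites))
  for (cc in conds) {
    cols <- mset$samples$condition == cc
    if (sum(cols) < min_reps)
      stop("condition '", cc, "' has fewer than min_reps samples")
    keep <- keep &
      rowSums(mset$total[, cols, drop = FALSE] >= min_cov) >= min_reps
  }
  keep
}

#' Bisulfite conversion efficiency from the chloroplast
#'
#' The chloroplast genome is unmethylated, so any methylated call there is
#' a conversion failure. Efficiency is 1 minus the pooled methylated/total
#' ratio over all chloroplast cytosines of a sample, reported pooled over
#' all contexts and per context.
#'
#' @param mset A [methylome_set()] whose `chloroplast` is set.
#' @return data.frame with columns `sample_id`, `context` (`"all"`, `"CG"`,
#'   `"CHG"`, `"CHH"`) and `efficiency`.
#' @export
conversion_efficiency <- function(mset) {
  if (is.na(mset$chloroplast)) stop("methylome_set has no chloroplast")
  cp <- mset$sites$chrom == mset$chloroplast
  if (!any(cp)) stop("no chloroplast sites present")
  if (all(colSums(mset$total[cp, , drop = FALSE]) == 0))
    stop("zero chloroplast coverage")
  one <- function(rows, label) {
    m <- colSums(mset$meth[rows, , drop = FALSE])
    t <- colSums(mset$total[rows, , drop = FALSE])
    data.frame(sample_id = mset$samples$sample_id, context = label,
               efficiency = ifelse(t > 0, 1 - m / t, NA_real_),
               stringsAsFactors = FALSE)
  }
  res <- one(cp, "all")
  for (ctx in c("CG", "CHG", "CHH"))
    res <- rbind(res, one(cp & mset$sites$context == ctx, ctx))
  rownames(res) <- NULL
  res
}

#' Pooled per-condition methylation levels
#'
#' Counts are pooled across replicates of a condition (sum of methylated
#' over sum of total), which weights replicates by their coverage.
#'
#' @param mset A [methylome_set()].
#' @param condition Condition label to pool.
#' @param which Optional logical/integer site subset (e.g. a coverage gate).
#' @return data.frame `chrom, pos, strand, context, meth, total, level`;
#'   `level` is `NA` where pooled total is 0.
#' @export
pooled_levels <- function(mset, condition, which = NULL) {
  cols <- mset$samples$condition == condition
  if (!any(cols)) stop("no samples in condition '", condition, "'")
  rows <- if (is.null(which)) seq_len(nrow(mset$sites)) else which
  m <- rowSums(mset$meth[rows, cols, drop = FALSE])
  t <- rowSums(mset$total[rows, cols, drop = FALSE])
  out <- mset$sites[rows, , drop = FALSE]
  out$meth <- m; out$total <- t; out$level <- site_level(m, t)
  rownames(out) <- NULL
  out
}

#' Genome-wide average methylation level per context
#'
#' @param levels A data.frame as from [pooled_levels()] (gated sites).
#' @return Named numeric vector of pooled-count mean levels per context.
#' @export
genome_mean_levels <- function(levels) {
  lv <- levels[!is.na(levels$level) & levels$context != "UNKNOWN", ]
  vapply(split(lv, lv$context), function(d) sum(d$meth) / sum(d$total),
         numeric(1))
}

#' Ten-bin methylation-level distribution per context
#'
#' Defined levels are placed in ten bins \[0,0.1), \[0.1,0.2), ...,
#' \[0.9,1.0\] (final bin closed), and per-context proportions returned.
#'
#' @param levels data.frame with `context` and `level` columns (gated,
#'   defined levels).
#' @return Matrix 10 x contexts of proportions; each column sums to 1.
#'   Contexts with no sites are omitted; empty input gives 0 columns.
#' @export
level_distribution <- function(levels) {
  lv <- levels[!is.na(levels$level) & levels$context != "UNKNOWN", ]
  bins <- paste0("[", seq(0, 0.9, 0.1), ",", seq(0.1, 1, 0.1),
                 c(rep(")", 9), "]"))
  if (nrow(lv) == 0)
    return(matrix(numeric(0), nrow = 10, ncol = 0,
                  dimnames = list(bins, NULL)))
  idx <- pmin(floor(lv$level * 10) + 1L, 10L)
  ctxs <- sort(unique(lv$context))
  out <- vapply(ctxs, function(cc) {
    tab <- tabulate(idx[lv$context == cc], nbins = 10L)
    tab / sum(tab)
  }, numeric(10))
  rownames(out) <- bins
  out
}

#' Fixed-window chromosome methylation tracks
#'
#' Non-overlapping windows tiled from position 0; each window's value is
#' the mean site level of the supplied (gated) sites inside it. Windows
#' containing no sites are omitted.
#'
#' @param levels data.frame with `chrom`, `pos`, `context`, `level`.
#' @param window Window width in bases (default 50000).
#' @return data.frame `chrom, start, end, context, value` (0-based
#'   half-open), suitable for [write_bedgraph()].
#' @export
genome_tracks <- function(levels, window = 50000) {
  if (window <= 0) stop("window must be positive")
  lv <- levels[!is.na(levels$level) & levels$context != "UNKNOWN", ]
  if (nrow(lv) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      value = numeric()))
  win <- lv$pos %/% window
  key <- paste(lv$chrom, lv$context, win, sep = "\r")
  agg <- tapply(lv$level, key, mean)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    start = as.integer(vapply(parts, `[`, character(1), 3L)) * as.integer(window),
    context = vapply(parts, `[`, character(1), 2L),
    value = as.numeric(agg), stringsAsFactors = FALSE)
  out$end <- out$start + as.integer(window)
  out <- out[order(out$context, out$chrom, out$start),
             c("chrom", "start", "end", "context", "value")]
  rownames(out) <- NULL
  out
}

#' Write a track as bedGraph (one file per context)
#'
#' @param track data.frame from [genome_tracks()].
#' @param prefix Output path prefix; files are named
#'   `<prefix>.<context>.bedGraph`.
#' @return Character vector of files written, invisibly.
#' @export
write_bedgraph <- function(track, prefix) {
  files <- character(0)
  for (cc in unique(track$context)) {
    f <- paste0(prefix, ".", cc, ".bedGraph")
    d <- track[track$context == cc, c("chrom", "start", "end", "value")]
    utils::write.table(d, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Write per-sample cytosine count tables
#'
#' One TSV per sample with header
#' `chrom pos strand context methylated total` (1-based positions).
#'
#' @param mset A [methylome_set()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_methylome_tables <- function(mset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stats::setNames(
    file.path(dir, paste0(mset$samples$sample_id, ".meth.tsv")),
    mset$samples$sample_id)
  for (j in seq_len(nrow(mset$samples))) {
    d <- mset$sites
    d$pos <- d$pos + 1L
    d$methylated <- mset$meth[, j]
    d$total <- mset$total[, j]
    utils::write.table(d, paths[j], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Read per-sample cytosine count tables into a methylome set
#'
#' All files must describe the same site universe (same `chrom`, `pos`,
#' `strand` rows in the same order), as written by
#' [write_methylome_tables()].
#'
#' @param paths Character vector of per-sample TSV paths.
#' @param samples Sample sheet data.frame (`sample_id`, `condition`,
#'   `organ`, `replicate`) aligned with `paths`.
#' @param chloroplast Chloroplast chromosome name, or `NA`.
#' @return A [methylome_set()].
#' @export
read_methylome_tables <- function(paths, samples, chloroplast = NA_character_) {
  stopifnot(length(paths) == nrow(samples))
  tabs <- lapply(paths, utils::read.table, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE)
  first <- tabs[[1]]
  key <- function(d) paste(d$chrom, d$pos, d$strand)
  for (i in seq_along(tabs))
    if (!identical(key(tabs[[i]]), key(first)))
      stop("sample tables disagree on the site universe: ", paths[i])
  sites <- first[, c("chrom", "pos", "strand", "context")]
  sites$pos <- sites$pos - 1L
  methylome_set(
    sites, samples,
    meth = vapply(tabs, `[[`, numeric(nrow(first)), "methylated"),
    total = vapply(tabs, `[[`, numeric(nrow(first)), "total"),
    chloroplast = chloroplast)
}
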