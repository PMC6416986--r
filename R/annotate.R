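#' Construct a gene-model table
#'
#' Genes are stored normalized: 0-based half-open `start < end` plus
#' `strand`. The transcription start site (TSS) is `start` for `+` genes
#' and `end` for `-` genes; the termination site (TTS) is the other end.
#'
#' @param gene_id Character vector of unique gene ids.
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open body coordinates, `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return data.frame of gene models.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand) {
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  if (any(end <= start)) stop("gene body must be non-empty (start < end)")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.frame(gene_id = as.character(gene_id), chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

#' Write gene models as BED6
#' @param genes Gene-model data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  out <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                    0L, genes$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED6 or GFF3
#'
#' BED is read as 0-based half-open with the name column as gene id. GFF3
#' rows with feature type `gene` are used, converting 1-based closed
#' coordinates and taking the `ID` attribute as gene id.
#'
#' @param path Path to a `.bed` or `.gff`/`.gff3` file.
#' @return Gene-model data.frame as from [gene_models()].
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    g <- utils::read.table(path, sep = "\t", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE)
    g <- g[g$V3 == "gene", ]
    id <- sub(".*ID=([^;]+).*", "\\1", g$V9)
    gene_models(id, g$V1, g$V4 - 1L, g$V5, g$V7)
  } else {
    g <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    gene_models(g$V4, g$V1, g$V2, g$V3, g$V6)
  }
}

# Strand-aware gene-associated regions as a GRanges with gene_id/region
# metadata. Flanks are truncated at position 0 and, when lengths are
# known, at the chromosome end.
.gene_regions <- function(genes, flank = 2000, seqlens = NULL) {
  plus <- genes$strand == "+"
  up_s <- ifelse(plus, genes$start - flank, genes$end)
  up_e <- ifelse(plus, genes$start, genes$end + flank)
  dn_s <- ifelse(plus, genes$end, genes$start - flank)
  dn_e <- ifelse(plus, genes$end + flank, genes$start)
  reg <- data.frame(
    chrom = rep(genes$chrom, 3),
    start = c(up_s, genes$start, dn_s),
    end = c(up_e, genes$end, dn_e),
    gene_id = rep(genes$gene_id, 3),
    region = rep(c("upstream", "body", "downstream"), each = nrow(genes)),
    stringsAsFactors = FALSE)
  reg$start <- pmax(reg$start, 0L)
  if (!is.null(seqlens))
    reg$end <- pmin(reg$end, seqlens[reg$chrom])
  reg <- reg[reg$end > reg$start, ]
  gr <- GenomicRanges::GRanges(
    reg$chrom, IRanges::IRanges(reg$start + 1L, reg$end))
  S4Vectors::mcols(gr)$gene_id <- reg$gene_id
  S4Vectors::mcols(gr)$region <- reg$region
  gr
}

#' Assign methylation features to gene-associated regions
#'
#' Each feature (a DmC position or a DMR interval) is assigned to every
#' gene whose body or strand-aware 2 kb flank it overlaps; features
#' touching no gene region are omitted. Upstream means 5' of the TSS on
#' the gene's strand, downstream 3' of the TTS.
#'
#' @param features data.frame with `chrom` and either `pos` (points) or
#'   `start`/`end` (0-based half-open intervals); extra columns are kept.
#' @param genes Gene-model data.frame.
#' @param flank Flank width in bp (default 2000).
#' @param seqlens Optional named chromosome lengths for flank truncation.
#' @return data.frame: the overlapping feature rows with added `gene_id`
#'   and `region` (`"upstream"`, `"body"`, `"downstream"`); one row per
#'   (feature, gene, region) pair.
#' @export
assign_region <- function(features, genes, flank = 2000, seqlens = NULL) {
  if (!is.null(features$pos)) {
    fs <- features$pos; fe <- features$pos + 1L
  } else {
    fs <- features$start; fe <- features$end
  }
  fgr <- GenomicRanges::GRanges(features$chrom,
                                IRanges::IRanges(fs + 1L, fe))
  rgr <- .gene_regions(genes, flank, seqlens)
  hits <- GenomicRanges::findOverlaps(fgr, rgr)
  out <- features[S4Vectors::queryHits(hits), , drop = FALSE]
  out$gene_id <- S4Vectors::mcols(rgr)$gene_id[S4Vectors::subjectHits(hits)]
  out$region <- S4Vectors::mcols(rgr)$region[S4Vectors::subjectHits(hits)]
  rownames(out) <- NULL
  out
}

#' Count genes affected per region, context and direction
#'
#' A gene is counted once per (region, context, direction) cell no matter
#' how many features hit it; a gene with both hyper and hypo features in
#' the same cell coordinates appears in both direction cells.
#'
#' @param assignments data.frame from [assign_region()] carrying `context`
#'   and `direction` columns.
#' @return data.frame `region, context, direction, n_genes`.
#' @export
genes_affected <- function(assignments) {
  grid <- expand.grid(region = c("upstream", "body", "downstream"),
                      context = c("CG", "CHG", "CHH"),
                      direction = c("hyper", "hypo"),
                      stringsAsFactors = FALSE)
  grid$n_genes <- vapply(seq_len(nrow(grid)), function(i) {
    sel <- assignments$region == grid$region[i] &
      assignments$context == grid$context[i] &
      assignments$direction == grid$direction[i]
    length(unique(assignments$gene_id[sel]))
  }, integer(1))
  grid
}

#' Metagene methylation profile
#'
#' Each gene body is rescaled to `body_bins` bins and the 2 kb flanks are
#' cut into `flank_bins` fixed-width bins; site levels are pooled over
#' genes per bin and context, oriented 5'->3' (minus-strand genes
#' contribute mirrored). Genes whose body is shorter than `body_bins`
#' bases are excluded.
#'
#' @param levels data.frame of gated site levels (`chrom`, `pos`,
#'   `context`, `level`), e.g. from [pooled_levels()].
#' @param genes Gene-model data.frame.
#' @param flank Flank width in bp (default 2000).
#' @param body_bins,flank_bins Bin counts (defaults 100 and 20).
#' @return data.frame `bin, segment, context, mean_level, n_sites` with
#'   `bin` running 1..(2*flank_bins + body_bins) from upstream end to
#'   downstream end.
#' @export
metagene_profile <- function(levels, genes, flank = 2000,
                             body_bins = 100, flank_bins = 20) {
  genes <- genes[genes$end - genes$start >= body_bins, ]
  lv <- levels[!is.na(levels$level) & levels$context != "UNKNOWN", ]
  n_bins <- 2L * flank_bins + body_bins
  empty <- data.frame(bin = integer(), segment = character(),
                      context = character(), mean_level = numeric(),
                      n_sites = integer())
  if (nrow(genes) == 0 || nrow(lv) == 0) return(empty)
  bw <- flank / flank_bins
  span <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start - flank, 0L) + 1L, genes$end + flank))
  sgr <- GenomicRanges::GRanges(lv$chrom, IRanges::IRanges(lv$pos + 1L,
                                                           lv$pos + 1L))
  hits <- GenomicRanges::findOverlaps(sgr, span)
  si <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  pos <- lv$pos[si]
  gs <- genes$start[gi]; ge <- genes$end[gi]
  plus <- genes$strand[gi] == "+"
  glen <- ge - gs
  # per-pair transcript-oriented segment offset
  up_off <- ifelse(plus, pos - (gs - flank), (ge + flank - 1) - pos)
  body_off <- ifelse(plus, pos - gs, ge - 1 - pos)
  dn_off <- ifelse(plus, pos - ge, (gs - 1) - pos)
  bin <- rep(NA_integer_, length(pos))
  in_body <- body_off >= 0 & body_off < glen
  bin[in_body] <- flank_bins +
    pmin(floor(body_off[in_body] / glen[in_body] * body_bins), body_bins - 1) + 1L
  in_up <- !in_body & up_off >= 0 & up_off < flank & body_off < 0
  bin[in_up] <- floor(up_off[in_up] / bw) + 1L
  in_dn <- !in_body & dn_off >= 0 & dn_off < flank
  bin[in_dn] <- flank_bins + body_bins + floor(dn_off[in_dn] / bw) + 1L
  ok <- !is.na(bin)
  key <- paste(bin[ok], lv$context[si][ok], sep = "\r")
  mean_l <- tapply(lv$level[si][ok], key, mean)
  n_s <- tapply(lv$level[si][ok], key, length)
  parts <- strsplit(names(mean_l), "\r", fixed = TRUE)
  out <- data.frame(
    bin = as.integer(vapply(parts, `[`, character(1), 1L)),
    context = vapply(parts, `[`, character(1), 2L),
    mean_level = as.numeric(mean_l), n_sites = as.integer(n_s),
    stringsAsFactors = FALSE)
  out$segment <- ifelse(out$bin <= flank_bins, "upstream",
                        ifelse(out$bin <= flank_bins + body_bins,
                               "body", "downstream"))
  out <- out[order(out$context, out$bin),
             c("bin", "segment", "context", "mean_level", "n_sites")]
  rownames(out) <- NULL
  out
}
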