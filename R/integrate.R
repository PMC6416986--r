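#' Join differential methylation onto differentially expressed genes
#'
#' For each DEG carrying at least one mapped DmC, the DmC level
#' differences are averaged per (region, context) cell, and the gene's
#' expression/methylation trend is classified from the signs of those
#' cell means versus the sign of the expression log2 fold-change.
#'
#' @param degs DEG table from [call_degs()].
#' @param assignments DmC region assignments from [assign_region()]
#'   (must carry `gene_id`, `region`, `context`, `diff`).
#' @return List with `records` (long data.frame: `gene_id, log2fc, region,
#'   context, mean_diff, n_dmcs`) and `genes` (per-gene data.frame:
#'   `gene_id, log2fc, trend`).
#' @export
join_dmc_deg <- function(degs, assignments) {
  deg_ids <- degs$gene_id[degs$is_deg]
  a <- assignments[assignments$gene_id %in% deg_ids, , drop = FALSE]
  if (nrow(a) == 0) {
    return(list(records = data.frame(gene_id = character(),
                                     log2fc = numeric(), region = character(),
                                     context = character(),
                                     mean_diff = numeric(),
                                     n_dmcs = integer()),
                genes = data.frame(gene_id = character(), log2fc = numeric(),
                                   trend = character())))
  }
  key <- paste(a$gene_id, a$region, a$context, sep = "\r")
  md <- tapply(a$diff, key, mean)
  nd <- tapply(a$diff, key, length)
  parts <- strsplit(names(md), "\r", fixed = TRUE)
  rec <- data.frame(
    gene_id = vapply(parts, `[`, character(1), 1L),
    region = vapply(parts, `[`, character(1), 2L),
    context = vapply(parts, `[`, character(1), 3L),
    mean_diff = as.numeric(md), n_dmcs = as.integer(nd),
    stringsAsFactors = FALSE)
  rec$log2fc <- degs$log2fc[match(rec$gene_id, degs$gene_id)]
  rec <- rec[, c("gene_id", "log2fc", "region", "context", "mean_diff",
                 "n_dmcs")]
  rec <- rec[order(rec$gene_id, rec$region, rec$context), ]
  rownames(rec) <- NULL
  genes <- unique(rec[, c("gene_id", "log2fc")])
  genes$trend <- vapply(seq_len(nrow(genes)), function(i)
    classify_trend(genes$log2fc[i],
                   rec$mean_diff[rec$gene_id == genes$gene_id[i]]),
    character(1))
  rownames(genes) <- NULL
  list(records = rec, genes = genes)
}

#' Classify the expression/methylation trend of a gene
#'
#' "Opposite" means every mapped methylation change runs against the
#' expression change (up-regulated with hypomethylation, or down-regulated
#' with hypermethylation); "consistent" means every change runs with it;
#' genes with region/context cells of conflicting sign are "mixed".
#' Cells with a mean difference of exactly 0 carry no sign and are
#' ignored; a gene whose cells are all 0 is unclassifiable (`NA`).
#'
#' @param log2fc Expression log2 fold-change of the gene.
#' @param mean_diffs Numeric vector of per-(region, context) mean DmC
#'   level differences.
#' @return `"opposite"`, `"consistent"`, `"mixed"` or `NA`.
#' @export
classify_trend <- function(log2fc, mean_diffs) {
  s <- sign(mean_diffs[mean_diffs != 0])
  if (length(s) == 0) return(NA_character_)
  e <- sign(log2fc)
  if (all(s == -e)) "opposite"
  else if (all(s == e)) "consistent"
  else "mixed"
}

#' Expression-methylation correlation per region and context
#'
#' Pearson and Spearman correlations between the expression log2
#' fold-change and the mean methylation difference over the genes in each
#' (region, context) cell; cells with fewer than 3 genes are `NA`.
#'
#' @param records Long record table from [join_dmc_deg()].
#' @return data.frame `region, context, n, pearson, pearson_p, spearman`.
#' @export
expression_methylation_correlation <- function(records) {
  grid <- expand.grid(region = c("upstream", "body", "downstream"),
                      context = c("CG", "CHG", "CHH"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    d <- records[records$region == grid$region[i] &
                 records$context == grid$context[i], ]
    if (nrow(d) < 3)
      return(data.frame(grid[i, ], n = nrow(d), pearson = NA_real_,
                        pearson_p = NA_real_, spearman = NA_real_))
    ct <- stats::cor.test(d$mean_diff, d$log2fc, method = "pearson")
    data.frame(grid[i, ], n = nrow(d),
               pearson = unname(ct$estimate), pearson_p = ct$p.value,
               spearman = stats::cor(d$mean_diff, d$log2fc,
                                     method = "spearman"))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Overlap of DEG and DmC-DEG sets with a reference gene set
#'
#' @param deg_ids DEG ids of the organ.
#' @param dmc_deg_ids DmC-bearing DEG ids; must be a subset of `deg_ids`.
#' @param reference_ids Reference catalog ids (e.g. a ROS-signaling or
#'   housekeeping set).
#' @param set_name Label for the reference set.
#' @return List with set sizes, pairwise and triple intersection counts,
#'   and the reference-set share of each input set.
#' @export
gene_set_overlap <- function(deg_ids, dmc_deg_ids, reference_ids,
                             set_name = "reference") {
  deg_ids <- unique(deg_ids); dmc_deg_ids <- unique(dmc_deg_ids)
  reference_ids <- unique(reference_ids)
  if (!all(dmc_deg_ids %in% deg_ids))
    stop("dmc_deg_ids must be a subset of deg_ids")
  deg_ref <- intersect(deg_ids, reference_ids)
  dmc_ref <- intersect(dmc_deg_ids, reference_ids)
  list(set_name = set_name,
       n_deg = length(deg_ids), n_dmc_deg = length(dmc_deg_ids),
       n_reference = length(reference_ids),
       deg_and_reference = length(deg_ref),
       dmc_deg_and_reference = length(dmc_ref),
       triple = length(intersect(dmc_ref, deg_ids)),
       deg_reference_share =
         if (length(deg_ids)) length(deg_ref) / length(deg_ids) else NA_real_,
       dmc_deg_reference_share =
         if (length(dmc_deg_ids)) length(dmc_ref) / length(dmc_deg_ids)
         else NA_real_)
}

#' Read a gene-set list from a one-column TSV
#' @param path Path to a TSV whose first column holds gene ids (header
#'   optional, detected by a `gene_id` first field).
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)[[1]]
  if (identical(tolower(x[1]), "gene_id")) x <- x[-1]
  unique(x)
}
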