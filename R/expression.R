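#' Construct an expression set
#'
#' @param counts Non-negative integer matrix, genes x samples, with gene
#'   ids as rownames.
#' @param samples data.frame (`sample_id`, `condition`, `organ`,
#'   `replicate`) aligned with the columns of `counts`.
#' @param gene_lengths Named numeric vector of transcript lengths (bp),
#'   one per gene.
#' @return An object of class `"expression_set"`.
#' @export
expression_set <- function(counts, samples, gene_lengths) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == nrow(samples),
            all(rownames(counts) %in% names(gene_lengths)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("zero library size")
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, samples = samples,
                 gene_lengths = gene_lengths[rownames(counts)]),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

#' Counts per million and FPKM
#'
#' CPM = count / library size x 1e6; FPKM = CPM x 1e3 / gene length.
#'
#' @param eset An [expression_set()].
#' @return List with matrices `cpm` and `fpkm`.
#' @export
cpm_fpkm <- function(eset) {
  lib <- colSums(eset$counts)
  if (any(lib == 0)) stop("zero library size")
  cpm <- sweep(eset$counts, 2, lib, "/") * 1e6
  if (any(eset$gene_lengths <= 0)) stop("gene lengths must be positive")
  fpkm <- cpm * 1e3 / eset$gene_lengths
  list(cpm = cpm, fpkm = fpkm)
}

#' Low-expression gate
#'
#' A gene is retained when its CPM exceeds `min_cpm` (strictly) in at
#' least `min_samples` libraries of the analysis.
#'
#' @param eset An [expression_set()].
#' @param min_cpm CPM threshold (default 5).
#' @param min_samples Minimum qualifying libraries (default 3).
#' @return Logical vector over genes.
#' @export
expression_gate <- function(eset, min_cpm = 5, min_samples = 3) {
  cpm <- cpm_fpkm(eset)$cpm
  rowSums(cpm > min_cpm) >= min_samples
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors (geometric mean 1); the
#' effective library size of a sample is library size x factor.
#'
#' @param counts Genes x samples count matrix.
#' @return Numeric vector of per-sample factors.
#' @export
normalize_tmm <- function(counts) {
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  edgeR::calcNormFactors(as.matrix(counts), method = "TMM")
}

# Per-gene NB dispersion by Cox-Reid adjusted profile likelihood on a
# log-spaced grid, shrunk toward the common value by weighting each
# gene's profile with the genewise-average profile (empirical Bayes;
# prior weight = prior_df / residual df). The CR adjustment
# (-0.5 log det information) removes the small-sample bias of plugging
# in estimated group means.
.dispersion_grid <- function() exp(seq(log(1e-4), log(4), length.out = 30))

.nb_apl_profile <- function(y, off, groups, grid) {
  apl <- matrix(0, nrow(y), length(grid))
  for (k in seq_along(grid)) {
    phi <- rep(grid[k], nrow(y))
    for (g in unique(groups)) {
      cols <- groups == g
      fit <- .nb_fit_mean(y[, cols, drop = FALSE], off[cols], phi,
                          max_iter = 25)
      mu <- exp(fit$beta) %o% exp(off[cols])
      info <- rowSums(mu / (1 + grid[k] * mu))
      apl[, k] <- apl[, k] + fit$loglik -
        0.5 * log(pmax(info, 1e-300))
    }
  }
  apl
}

.estimate_dispersion <- function(counts, groups, eff_lib, prior_df = 10) {
  grid <- .dispersion_grid()
  apl <- .nb_apl_profile(counts, log(eff_lib), groups, grid)
  df_res <- max(ncol(counts) - length(unique(groups)), 1)
  prior_n <- prior_df / df_res
  score <- apl + prior_n * matrix(colMeans(apl), nrow(counts),
                                  length(grid), byrow = TRUE)
  grid[max.col(score, ties.method = "first")]
}

# Vectorized Newton fit of a single NB mean with log link and per-sample
# offsets; returns beta and the profile log-likelihood per gene.
.nb_fit_mean <- function(y, off, phi, max_iter = 50, tol = 1e-10) {
  eo <- exp(off)
  rs <- rowSums(y)
  beta <- ifelse(rs > 0, log(rs / sum(eo)), -30)
  converged <- rep(FALSE, length(beta))
  for (it in seq_len(max_iter)) {
    mu <- exp(beta) %o% eo
    denom <- 1 + phi * mu
    U <- rowSums((y - mu) / denom)
    J <- rowSums(mu / denom)
    step <- ifelse(J > 0, U / J, 0)
    step <- pmax(pmin(step, 3), -3)
    beta <- beta + step
    converged <- abs(step) < tol | rs == 0
    if (all(converged)) break
  }
  mu <- exp(beta) %o% eo
  ll <- .nb_loglik(y, mu, phi)
  list(beta = beta, loglik = ll, converged = converged)
}

.nb_loglik <- function(y, mu, phi) {
  ll <- matrix(0, nrow(y), ncol(y))
  pois <- phi < 1e-8
  mu <- pmax(mu, 1e-12)
  if (any(pois))
    ll[pois, ] <- stats::dpois(y[pois, , drop = FALSE],
                               mu[pois, , drop = FALSE], log = TRUE)
  if (any(!pois))
    ll[!pois, ] <- stats::dnbinom(y[!pois, , drop = FALSE],
                                  size = 1 / phi[!pois],
                                  mu = mu[!pois, , drop = FALSE], log = TRUE)
  rowSums(ll)
}

#' Negative-binomial differential expression test
#'
#' Per gene, an NB model with log link and effective-library offsets is
#' fitted under the null (one mean) and the alternative (one mean per
#' condition); the condition effect is assessed by a likelihood-ratio test
#' on 1 degree of freedom. Dispersions are method-of-moments estimates
#' shrunk toward the common value (empirical-Bayes style, `prior_df`
#' pseudo-degrees of freedom). The log2 fold-change is the difference of
#' fitted group means, test over control.
#'
#' @param eset An [expression_set()] (typically already gated).
#' @param test,control Condition labels (defaults `"flight"`, `"ground"`).
#' @param norm_factors Optional TMM factors; computed when `NULL`.
#' @param prior_df Dispersion-shrinkage prior degrees of freedom.
#' @return data.frame `gene_id, log2fc, p_value, dispersion, converged`.
#' @export
nb_test <- function(eset, test = "flight", control = "ground",
                    norm_factors = NULL, prior_df = 10) {
  cond <- eset$samples$condition
  if (sum(cond == test) < 2 || sum(cond == control) < 2)
    stop("need at least 2 replicates per condition")
  y <- eset$counts
  if (is.null(norm_factors)) norm_factors <- normalize_tmm(y)
  eff_lib <- colSums(y) * norm_factors
  off <- log(eff_lib)
  phi <- .estimate_dispersion(y, cond, eff_lib, prior_df)
  fit0 <- .nb_fit_mean(y, off, phi)
  ft <- .nb_fit_mean(y[, cond == test, drop = FALSE],
                     off[cond == test], phi)
  fc <- .nb_fit_mean(y[, cond == control, drop = FALSE],
                     off[cond == control], phi)
  lrt <- pmax(2 * (ft$loglik + fc$loglik - fit0$loglik), 0)
  converged <- ft$converged & fc$converged & fit0$converged
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  p[!converged] <- 1
  data.frame(gene_id = rownames(y),
             log2fc = (ft$beta - fc$beta) / log(2),
             p_value = p, dispersion = phi, converged = converged,
             stringsAsFactors = FALSE)
}

#' Call differentially expressed genes (DEGs)
#'
#' A DEG satisfies `q < fdr` (Benjamini-Hochberg within the organ),
#' absolute fold-change of at least `min_fold`, and mean FPKM above 0 in
#' at least one condition group.
#'
#' @param res Result of [nb_test()].
#' @param eset The [expression_set()] the test was run on.
#' @param test,control Condition labels.
#' @param fdr FDR threshold (default 0.05).
#' @param min_fold Fold-change threshold (default 2; boundary included).
#' @return `res` with added `q_value`, per-condition `mean_cpm_*` /
#'   `mean_fpkm_*` and logical `is_deg`.
#' @export
call_degs <- function(res, eset, test = "flight", control = "ground",
                      fdr = 0.05, min_fold = 2) {
  cf <- cpm_fpkm(eset)
  tcols <- eset$samples$condition == test
  ccols <- eset$samples$condition == control
  res$q_value <- bh_adjust(res$p_value)
  res$mean_cpm_test <- rowMeans(cf$cpm[, tcols, drop = FALSE])
  res$mean_cpm_control <- rowMeans(cf$cpm[, ccols, drop = FALSE])
  res$mean_fpkm_test <- rowMeans(cf$fpkm[, tcols, drop = FALSE])
  res$mean_fpkm_control <- rowMeans(cf$fpkm[, ccols, drop = FALSE])
  res$is_deg <- res$q_value < fdr &
    abs(res$log2fc) >= log2(min_fold) &
    pmax(res$mean_fpkm_test, res$mean_fpkm_control) > 0
  res
}

#' Two-organ DEG Venn counts
#'
#' @param deg_ids_a,deg_ids_b Character vectors of DEG ids for the two
#'   organs.
#' @return Named integer vector `n_a, n_b, shared, union`.
#' @export
deg_venn <- function(deg_ids_a, deg_ids_b) {
  c(n_a = length(deg_ids_a), n_b = length(deg_ids_b),
    shared = length(intersect(deg_ids_a, deg_ids_b)),
    union = length(union(deg_ids_a, deg_ids_b)))
}

#' Read a count matrix and sample sheet
#'
#' The count matrix TSV has gene ids in the first column and sample ids as
#' header; the sample sheet TSV has columns `sample_id`, `condition`,
#' `organ`, `replicate`; the gene-length TSV has `gene_id`, `length`.
#'
#' @param counts_path,samples_path,lengths_path File paths.
#' @return An [expression_set()].
#' @export
read_expression_tables <- function(counts_path, samples_path, lengths_path) {
  cnt <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                           row.names = 1, check.names = FALSE)
  smp <- utils::read.table(samples_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  len <- utils::read.table(lengths_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", "condition", "organ", "replicate"),
                     names(smp))
  if (length(missing))
    stop("sample sheet lacks fields: ", paste(missing, collapse = ", "))
  cnt <- as.matrix(cnt[, smp$sample_id, drop = FALSE])
  expression_set(cnt, smp, stats::setNames(len$length, len$gene_id))
}

#' Write an expression set as TSV files
#' @param eset An [expression_set()].
#' @param dir Output directory.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_expression_tables <- function(eset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             lengths = file.path(dir, "gene_lengths.tsv"))
  cnt <- data.frame(gene_id = rownames(eset$counts), eset$counts,
                    check.names = FALSE)
  utils::write.table(cnt, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(eset$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(eset$gene_lengths),
               length = as.numeric(eset$gene_lengths)),
    paths["lengths"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
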