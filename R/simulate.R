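#' Simulation configuration
#'
#' Defaults emulate the study design this package targets: two conditions
#' (spaceflight vs ground control) with three biological replicates of one
#' organ, a small random nuclear genome plus a fully unmethylated
#' chloroplast, context-dependent baseline methylation (bimodal CG around
#' a 0.24 mean, unimodal CHG 0.10 and CHH 0.05), imperfect bisulfite
#' conversion at 99%, planted DmCs and DMRs, and NB-distributed expression
#' counts with planted DEGs partially coupled to gene-body CG methylation
#' changes.
#'
#' @param seed Integer seed; all randomness of the generators flows from
#'   it.
#' @param n_chroms,chrom_length,chloroplast_length Nuclear chromosome
#'   count / length and chloroplast length in bases.
#' @param n_genes,gene_length_mean Gene count and mean gene length.
#' @param n_replicates Replicates per condition (default 3).
#' @param depth_mean Mean read depth per cytosine (Poisson).
#' @param conversion_efficiency Bisulfite conversion fraction in \[0, 1\].
#' @param baseline_levels Named vector of mean methylation levels per
#'   context.
#' @param n_true_dmcs,dmc_effect Count of planted single-site changes and
#'   their methylation-level shift.
#' @param n_true_dmrs,dmr_width Count and width of planted regions.
#' @param n_true_degs,deg_log2fc Count of planted DEGs and their absolute
#'   log2 fold-change.
#' @param nb_dispersion NB dispersion of expression counts (0 = Poisson).
#' @param expr_mean_log,expr_sd_log Log-normal parameters of baseline
#'   gene expression means.
#' @param coupling_fraction Fraction of planted DEGs that also carry an
#'   opposite-sign gene-body CG methylation change.
#' @param organ Organ label stamped on the samples.
#' @param conditions Length-2 character vector, test condition first.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 250000L,
                       chloroplast_length = 20000L, n_genes = 100L,
                       gene_length_mean = 2000L, n_replicates = 3L,
                       depth_mean = 30, conversion_efficiency = 0.99,
                       baseline_levels = c(CG = 0.24, CHG = 0.10, CHH = 0.05),
                       n_true_dmcs = 200L, dmc_effect = 0.4,
                       n_true_dmrs = 20L, dmr_width = 300L,
                       n_true_degs = 50L, deg_log2fc = 2,
                       nb_dispersion = 0.1, expr_mean_log = log(150),
                       expr_sd_log = 1.2, coupling_fraction = 0.5,
                       organ = "root",
                       conditions = c("flight", "ground")) {
  cfg <- list(seed = as.integer(seed), n_chroms = n_chroms,
              chrom_length = chrom_length,
              chloroplast_length = chloroplast_length, n_genes = n_genes,
              gene_length_mean = gene_length_mean,
              n_replicates = n_replicates, depth_mean = depth_mean,
              conversion_efficiency = conversion_efficiency,
              baseline_levels = baseline_levels,
              n_true_dmcs = n_true_dmcs, dmc_effect = dmc_effect,
              n_true_dmrs = n_true_dmrs, dmr_width = dmr_width,
              n_true_degs = n_true_degs, deg_log2fc = deg_log2fc,
              nb_dispersion = nb_dispersion,
              expr_mean_log = expr_mean_log, expr_sd_log = expr_sd_log,
              coupling_fraction = coupling_fraction, organ = organ,
              conditions = conditions)
  with(cfg, {
    stopifnot(n_chroms >= 1, chrom_length > 0, n_genes >= 0,
              n_replicates >= 1, depth_mean > 0,
              conversion_efficiency >= 0, conversion_efficiency <= 1,
              all(baseline_levels >= 0 & baseline_levels <= 1),
              abs(dmc_effect) <= 1, nb_dispersion >= 0,
              coupling_fraction >= 0, coupling_fraction <= 1,
              length(conditions) == 2)
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome with non-overlapping gene models
#'
#' Uniform-random nuclear chromosomes plus one chloroplast named `ChrC`;
#' genes are placed without overlap on both strands of the nuclear
#' chromosomes.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a [genome()]) and `genes` (a
#'   [gene_models()] data.frame).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  chroms <- paste0("Chr", seq_len(config$n_chroms))
  seqs <- stats::setNames(
    c(vapply(chroms, function(i) rand_seq(config$chrom_length),
             character(1)),
      rand_seq(config$chloroplast_length)),
    c(chroms, "ChrC"))
  g <- genome(seqs, chloroplast = "ChrC")
  if (config$n_genes == 0)
    return(list(genome = g, genes = gene_models(character(0), character(0),
                                                integer(0), integer(0),
                                                character(0))[0, ]))
  lens <- pmax(round(stats::rgamma(config$n_genes, shape = 6,
                                   rate = 6 / config$gene_length_mean)), 300)
  chrom <- sample(chroms, config$n_genes, replace = TRUE)
  starts <- integer(config$n_genes)
  placed <- lapply(chroms, function(x) cbind(integer(0), integer(0)))
  names(placed) <- chroms
  for (i in seq_len(config$n_genes)) {
    ok <- FALSE
    for (try in 1:500) {
      s <- sample.int(config$chrom_length - lens[i], 1) - 1L
      e <- s + lens[i]
      iv <- placed[[chrom[i]]]
      if (nrow(iv) == 0 || all(e <= iv[, 1] | s >= iv[, 2])) {
        placed[[chrom[i]]] <- rbind(iv, c(s, e))
        starts[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place genes without overlap; ",
                  "reduce n_genes or gene_length_mean")
  }
  genes <- gene_models(sprintf("G%04d", seq_len(config$n_genes)), chrom,
                       starts, starts + lens,
                       sample(c("+", "-"), config$n_genes, replace = TRUE))
  list(genome = g, genes = genes)
}

# Draw per-site true baseline methylation levels. CG is a bimodal mixture
# of a highly methylated (Beta(20, 3)) and an essentially unmethylated
# (Beta(0.5, 30)) component with the mixing weight chosen to hit the
# configured mean; CHG/CHH are unimodal Beta with concentration 20.
.draw_baseline <- function(context, baseline_levels) {
  n <- length(context)
  lev <- numeric(n)
  cg <- context == "CG"
  if (any(cg)) {
    mu_hi <- 20 / 23; mu_lo <- 0.5 / 30.5
    p_hi <- min(max((baseline_levels[["CG"]] - mu_lo) / (mu_hi - mu_lo), 0), 1)
    hi <- stats::runif(sum(cg)) < p_hi
    lev[cg] <- ifelse(hi, stats::rbeta(sum(cg), 20, 3),
                      stats::rbeta(sum(cg), 0.5, 30))
  }
  for (ctx in c("CHG", "CHH")) {
    rows <- context == ctx
    if (!any(rows)) next
    m <- baseline_levels[[ctx]]
    lev[rows] <- stats::rbeta(sum(rows), m * 20, (1 - m) * 20)
  }
  other <- !(context %in% c("CG", "CHG", "CHH"))
  if (any(other)) {
    m <- baseline_levels[["CHH"]]
    lev[other] <- stats::rbeta(sum(other), m * 20, (1 - m) * 20)
  }
  lev
}

# Shift levels by +/- effect, choosing the direction that stays in [0, 1]
# (random when both directions are feasible).
.planted_shift <- function(level, effect, sign = NULL) {
  if (is.null(sign)) {
    up_ok <- level + effect <= 1
    dn_ok <- level - effect >= 0
    sign <- ifelse(up_ok & dn_ok, base::sign(stats::runif(length(level)) - 0.5),
                   ifelse(up_ok, 1, -1))
    sign[sign == 0] <- 1
  }
  list(level = pmin(pmax(level + sign * effect, 0), 1), sign = sign)
}

# Plant a coherent regional shift of a fixed sign. A hypomethylated
# region only exists where there is methylation to lose, so the ground
# state of a hypo region is re-drawn methylated (effect + headroom);
# for hyper regions only the individually infeasible (already highly
# methylated) sites are re-based low. Returns updated (control, test)
# levels for the region's sites.
.plant_region <- function(lev_control, effect, sign) {
  n <- length(lev_control)
  if (sign < 0) {
    ground <- effect + (1 - effect) * stats::rbeta(n, 2, 4)
    list(control = ground, test = ground - effect)
  } else {
    ground <- lev_control
    bad <- ground + effect > 1
    ground[bad] <- (1 - effect) * stats::rbeta(sum(bad), 1, 3)
    list(control = ground, test = ground + effect)
  }
}

#' Simulate per-sample bisulfite count tables with planted truth
#'
#' True levels are drawn per context from the configured baselines and
#' shared across replicates; the test condition shifts planted DmC sites
#' and all sites inside planted DMR intervals by `dmc_effect`. The
#' chloroplast is fully unmethylated, so its observed methylated counts
#' are pure conversion failure: every chloroplast cytosine reads
#' methylated with probability `1 - conversion_efficiency`. Per site and
#' sample, total counts are Poisson(`depth_mean`) and methylated counts
#' Binomial(total, effective level).
#'
#' @param sim Output of [simulate_genome()] (genome + genes).
#' @param config A [sim_config()].
#' @param expr_truth Optional expression ground truth (from
#'   [simulate_expression()]); its coupled genes receive an opposite-sign
#'   gene-body CG methylation shift in the test condition.
#' @return List with `mset` (a [methylome_set()]) and `truth` (list:
#'   `dmc_sites` data.frame, `dmr_intervals` data.frame, `coupled_genes`).
#' @export
simulate_methylomes <- function(sim, config, expr_truth = NULL) {
  set.seed(config$seed + 1L)
  g <- sim$genome
  sites <- enumerate_cytosine_sites(g)
  n <- nrow(sites)
  nuclear <- sites$chrom != g$chloroplast
  informative <- nuclear & sites$context != "UNKNOWN"
  lev_control <- .draw_baseline(sites$context, config$baseline_levels)
  lev_test <- lev_control

  # planted single-site DmCs
  dmc_idx <- integer(0)
  if (config$n_true_dmcs > 0) {
    dmc_idx <- sample(which(informative), config$n_true_dmcs)
    sh <- .planted_shift(lev_control[dmc_idx], config$dmc_effect)
    lev_test[dmc_idx] <- sh$level
    dmc_sign <- sh$sign
  } else dmc_sign <- numeric(0)

  # planted DMR intervals: coherent shift of every informative site inside
  dmr_intervals <- data.frame(chrom = character(0), start = integer(0),
                              end = integer(0), direction = character(0))
  if (config$n_true_dmrs > 0) {
    chroms <- setdiff(names(g$sequences), g$chloroplast)
    cl <- seq_lengths(g)
    dmr_chrom <- sample(chroms, config$n_true_dmrs, replace = TRUE)
    dmr_start <- vapply(dmr_chrom, function(cc)
      sample.int(cl[[cc]] - config$dmr_width, 1) - 1L, integer(1))
    dmr_sign <- sample(c(1, -1), config$n_true_dmrs, replace = TRUE)
    for (i in seq_len(config$n_true_dmrs)) {
      rows <- which(informative & sites$chrom == dmr_chrom[i] &
                    sites$pos >= dmr_start[i] &
                    sites$pos < dmr_start[i] + config$dmr_width)
      pl <- .plant_region(lev_control[rows], config$dmc_effect, dmr_sign[i])
      lev_control[rows] <- pl$control
      lev_test[rows] <- pl$test
    }
    dmr_intervals <- data.frame(
      chrom = dmr_chrom, start = as.integer(dmr_start),
      end = as.integer(dmr_start + config$dmr_width),
      direction = ifelse(dmr_sign > 0, "hyper", "hypo"),
      stringsAsFactors = FALSE)
  }

  # methylation-expression coupling: coupled DEGs get an opposite-sign
  # gene-body CG shift in the test condition
  coupled <- character(0)
  if (!is.null(expr_truth) && length(expr_truth$coupled_genes) > 0) {
    coupled <- expr_truth$coupled_genes
    for (gid in coupled) {
      gm <- sim$genes[sim$genes$gene_id == gid, ]
      rows <- which(informative & sites$context == "CG" &
                    sites$chrom == gm$chrom &
                    sites$pos >= gm$start & sites$pos < gm$end)
      s <- -sign(expr_truth$deg_log2fc[[gid]])
      pl <- .plant_region(lev_control[rows], config$dmc_effect, s)
      lev_control[rows] <- pl$control
      lev_test[rows] <- pl$test
    }
  }

  # chloroplast: unmethylated; conversion failure is the only signal
  cp <- sites$chrom == g$chloroplast
  lev_control[cp] <- lev_test[cp] <- 1 - config$conversion_efficiency

  n_rep <- config$n_replicates
  samples <- data.frame(
    sample_id = paste0(rep(config$conditions, each = n_rep), "_",
                       config$organ, "_", rep(seq_len(n_rep), 2)),
    condition = rep(config$conditions, each = n_rep),
    organ = config$organ, replicate = rep(seq_len(n_rep), 2),
    stringsAsFactors = FALSE)
  meth <- total <- matrix(0L, n, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    lev <- if (samples$condition[j] == config$conditions[1]) lev_test
           else lev_control
    tj <- stats::rpois(n, config$depth_mean)
    meth[, j] <- stats::rbinom(n, tj, lev)
    total[, j] <- tj
  }
  truth <- list(
    dmc_sites = if (length(dmc_idx))
      data.frame(sites[dmc_idx, c("chrom", "pos", "strand", "context")],
                 direction = ifelse(dmc_sign > 0, "hyper", "hypo"),
                 row.names = NULL)
    else data.frame(chrom = character(0), pos = integer(0),
                    strand = character(0), context = character(0),
                    direction = character(0)),
    dmr_intervals = dmr_intervals,
    coupled_genes = coupled,
    level_test = lev_test, level_control = lev_control)
  list(mset = methylome_set(sites, samples, meth, total,
                            chloroplast = g$chloroplast),
       truth = truth)
}

#' Simulate an expression count matrix with planted DEGs
#'
#' Baseline means are log-normal; counts are NB with the configured
#' dispersion (Poisson at dispersion 0) around mean x library factor;
#' planted DEGs multiply the test-condition mean by `2^(+/- deg_log2fc)`.
#' A `coupling_fraction` of the planted DEGs is marked as coupled to
#' methylation (consumed by [simulate_methylomes()]).
#'
#' @param genes Gene-model data.frame (ids and lengths are taken from it).
#' @param config A [sim_config()].
#' @return List with `eset` (an [expression_set()]) and `truth` (list:
#'   `deg_log2fc` named numeric, `coupled_genes` character).
#' @export
simulate_expression <- function(genes, config) {
  set.seed(config$seed + 2L)
  n_g <- nrow(genes)
  if (n_g == 0) stop("no genes to simulate expression for")
  mu0 <- stats::rlnorm(n_g, config$expr_mean_log, config$expr_sd_log)
  names(mu0) <- genes$gene_id
  deg_ids <- character(0); l2fc <- numeric(0)
  if (config$n_true_degs > 0) {
    deg_ids <- sample(genes$gene_id, min(config$n_true_degs, n_g))
    l2fc <- stats::setNames(
      sample(c(1, -1), length(deg_ids), replace = TRUE) * config$deg_log2fc,
      deg_ids)
  }
  coupled <- if (length(deg_ids))
    deg_ids[seq_len(round(config$coupling_fraction * length(deg_ids)))]
  else character(0)
  n_rep <- config$n_replicates
  samples <- data.frame(
    sample_id = paste0(rep(config$conditions, each = n_rep), "_",
                       config$organ, "_", rep(seq_len(n_rep), 2)),
    condition = rep(config$conditions, each = n_rep),
    organ = config$organ, replicate = rep(seq_len(n_rep), 2),
    stringsAsFactors = FALSE)
  libf <- stats::runif(nrow(samples), 0.7, 1.3)
  counts <- matrix(0L, n_g, nrow(samples),
                   dimnames = list(genes$gene_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- mu0
    if (samples$condition[j] == config$conditions[1] && length(deg_ids))
      mu[deg_ids] <- mu[deg_ids] * 2^l2fc
    mu <- mu * libf[j]
    counts[, j] <- if (config$nb_dispersion == 0) stats::rpois(n_g, mu)
                   else stats::rnbinom(n_g, mu = mu,
                                       size = 1 / config$nb_dispersion)
  }
  lens <- stats::setNames(genes$end - genes$start, genes$gene_id)
  list(eset = expression_set(counts, samples, lens),
       truth = list(deg_log2fc = as.list(l2fc), coupled_genes = coupled))
}

#' Simulate a complete synthetic dataset
#'
#' Genome + gene models, expression counts with planted DEGs, and
#' bisulfite count tables with planted DmCs/DMRs and methylation changes
#' coupled to a fraction of the planted DEGs.
#'
#' @param config A [sim_config()].
#' @return List: `genome`, `genes`, `mset`, `eset`, `truth` (merged
#'   ground-truth list).
#' @export
simulate_dataset <- function(config = sim_config()) {
  sim <- simulate_genome(config)
  expr <- if (nrow(sim$genes) > 0) simulate_expression(sim$genes, config)
          else NULL
  me <- simulate_methylomes(sim, config, expr_truth = expr$truth)
  truth <- me$truth
  truth$deg_log2fc <- if (is.null(expr)) list() else expr$truth$deg_log2fc
  list(genome = sim$genome, genes = sim$genes, mset = me$mset,
       eset = expr$eset, truth = truth)
}

#' Simulate a flat site panel for false-discovery benchmarking
#'
#' A panel of independent cytosines (no genome needed): a `signal_fraction`
#' of sites carries a planted level difference of `delta` between the two
#' conditions, the rest are null (identical levels). Baselines follow the
#' configured context mixture; counts are Poisson(`depth`) totals with
#' binomial methylated counts.
#'
#' @param n_sites Number of sites.
#' @param signal_fraction Fraction of sites with a planted difference.
#' @param delta Planted level difference.
#' @param depth Mean coverage per replicate.
#' @param n_reps Replicates per condition.
#' @param seed Integer seed.
#' @param baseline_levels Context mean levels as in [sim_config()].
#' @return List with `mset` (a [methylome_set()], sites spaced 1 kb apart
#'   so windows never pool them) and `is_signal` logical truth vector.
#' @export
simulate_dmc_benchmark <- function(n_sites = 50000, signal_fraction = 0.1,
                                   delta = 0.3, depth = 100, n_reps = 3,
                                   seed = 1L,
                                   baseline_levels = c(CG = 0.24, CHG = 0.10,
                                                       CHH = 0.05)) {
  set.seed(seed)
  context <- sample(c("CG", "CHG", "CHH"), n_sites, replace = TRUE,
                    prob = c(0.15, 0.15, 0.7))
  sites <- data.frame(chrom = "ChrS", pos = (seq_len(n_sites) - 1L) * 1000L,
                      strand = "+", context = context,
                      stringsAsFactors = FALSE)
  lev_control <- .draw_baseline(context, baseline_levels)
  lev_test <- lev_control
  n_sig <- round(signal_fraction * n_sites)
  is_signal <- rep(FALSE, n_sites)
  if (n_sig > 0) {
    idx <- sample.int(n_sites, n_sig)
    is_signal[idx] <- TRUE
    lev_test[idx] <- .planted_shift(lev_control[idx], delta)$level
  }
  samples <- data.frame(
    sample_id = paste0(rep(c("flight", "ground"), each = n_reps), "_",
                       rep(seq_len(n_reps), 2)),
    condition = rep(c("flight", "ground"), each = n_reps),
    organ = "sim", replicate = rep(seq_len(n_reps), 2),
    stringsAsFactors = FALSE)
  meth <- total <- matrix(0L, n_sites, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    lev <- if (samples$condition[j] == "flight") lev_test else lev_control
    tj <- stats::rpois(n_sites, depth)
    meth[, j] <- stats::rbinom(n_sites, tj, lev)
    total[, j] <- tj
  }
  list(mset = methylome_set(sites, samples, meth, total),
       is_signal = is_signal)
}
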