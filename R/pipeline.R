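#' Run the full differential methylome / transcriptome pipeline
#'
#' Orchestrates, for one organ: coverage gating, conversion-efficiency
#' estimation, genome-wide level summaries, DmC and DMR calling, gene
#' annotation (upstream / body / downstream), metagene profiles,
#' differential expression, and methylation-expression integration.
#'
#' @param mset A [methylome_set()] (two conditions).
#' @param eset An [expression_set()] for the same samples design, or
#'   `NULL` to skip the expression and integration stages.
#' @param genes Gene-model data.frame ([gene_models()]).
#' @param genome Optional [genome()] for chromosome-name validation and
#'   flank truncation.
#' @param output_dir Optional directory; when given, all stage outputs are
#'   written as TSV/BED/bedGraph files.
#' @param min_cov,min_reps Coverage gate (defaults 10 reads, 2 replicates).
#' @param dmc_fdr Site-level FDR threshold (default 0.01).
#' @param dmr_window,dmr_min_dmcs,dmr_min_diff,dmr_alpha DMR gates
#'   (defaults 100 bp, 4 DmCs, 0.2, 0.01).
#' @param flank Gene flank width (default 2000 bp).
#' @param min_cpm,min_cpm_samples Expression gate (defaults 5, 3).
#' @param deg_fdr,min_fold DEG thresholds (defaults 0.05 and 2-fold).
#' @param track_window Chromosome track window (default 50 kb).
#' @param test,control Condition labels.
#' @param gene_sets Optional named list of reference gene-id vectors for
#'   overlap reports.
#' @return A list bundle with every stage's tables and summary counts.
#' @export
run_pipeline <- function(mset, eset, genes, genome = NULL,
                         output_dir = NULL,
                         min_cov = 10, min_reps = 2, dmc_fdr = 0.01,
                         dmr_window = 100, dmr_min_dmcs = 4,
                         dmr_min_diff = 0.2, dmr_alpha = 0.01,
                         flank = 2000, min_cpm = 5, min_cpm_samples = 3,
                         deg_fdr = 0.05, min_fold = 2,
                         track_window = 50000,
                         test = "flight", control = "ground",
                         gene_sets = list()) {
  seqlens <- NULL
  if (!is.null(genome)) {
    seqlens <- seq_lengths(genome)
    bad <- setdiff(unique(mset$sites$chrom), names(seqlens))
    if (length(bad))
      stop("methylome chromosomes absent from genome: ",
           paste(bad, collapse = ", "))
  }
  if (nrow(genes) > 0) {
    bad <- setdiff(unique(genes$chrom), unique(mset$sites$chrom))
    if (length(bad))
      stop("gene-model chromosomes absent from methylome: ",
           paste(bad, collapse = ", "))
  }

  gate <- coverage_gate(mset, min_cov = min_cov, min_reps = min_reps)
  conv <- if (!is.na(mset$chloroplast)) conversion_efficiency(mset) else NULL

  lev_test <- pooled_levels(mset, test, which = gate)
  lev_control <- pooled_levels(mset, control, which = gate)
  nuclear <- if (is.na(mset$chloroplast)) rep(TRUE, nrow(lev_test))
             else lev_test$chrom != mset$chloroplast
  mean_levels <- list(test = genome_mean_levels(lev_test[nuclear, ]),
                      control = genome_mean_levels(lev_control[nuclear, ]))
  distributions <- list(test = level_distribution(lev_test[nuclear, ]),
                        control = level_distribution(lev_control[nuclear, ]))
  tracks <- list(test = genome_tracks(lev_test[nuclear, ], track_window),
                 control = genome_tracks(lev_control[nuclear, ], track_window))

  dmc_tbl <- call_dmcs(dmc_test(mset, gate & (if (is.na(mset$chloroplast))
    TRUE else mset$sites$chrom != mset$chloroplast),
    test = test, control = control), fdr = dmc_fdr)
  dmrs <- call_dmrs(dmc_tbl, window = dmr_window, min_dmcs = dmr_min_dmcs,
                    min_diff = dmr_min_diff, alpha = dmr_alpha)
  diff_summary <- summarize_differential(dmc_tbl, dmrs)

  dmcs <- dmc_tbl[dmc_tbl$is_dmc, ]
  dmc_assign <- assign_region(dmcs, genes, flank = flank, seqlens = seqlens)
  dmr_assign <- assign_region(dmrs, genes, flank = flank, seqlens = seqlens)
  affected <- list(dmc = genes_affected(dmc_assign),
                   dmr = genes_affected(dmr_assign))
  profiles <- list(
    test = metagene_profile(lev_test[nuclear, ], genes, flank = flank),
    control = metagene_profile(lev_control[nuclear, ], genes, flank = flank))

  degs <- integration <- correlations <- overlaps <- NULL
  if (!is.null(eset)) {
    keep <- expression_gate(eset, min_cpm = min_cpm,
                            min_samples = min_cpm_samples)
    gated <- expression_set(eset$counts[keep, , drop = FALSE],
                            eset$samples, eset$gene_lengths[keep])
    degs <- call_degs(nb_test(gated, test = test, control = control),
                      gated, test = test, control = control,
                      fdr = deg_fdr, min_fold = min_fold)
    integration <- join_dmc_deg(degs, dmc_assign)
    correlations <- expression_methylation_correlation(integration$records)
    if (length(gene_sets)) {
      deg_ids <- degs$gene_id[degs$is_deg]
      dmc_deg_ids <- integration$genes$gene_id
      overlaps <- lapply(names(gene_sets), function(nm)
        gene_set_overlap(deg_ids, dmc_deg_ids, gene_sets[[nm]], nm))
      names(overlaps) <- names(gene_sets)
    }
  }

  res <- list(gate = gate, conversion = conv, mean_levels = mean_levels,
              level_distributions = distributions, tracks = tracks,
              dmc_table = dmc_tbl, dmrs = dmrs,
              diff_summary = diff_summary,
              dmc_assignments = dmc_assign, dmr_assignments = dmr_assign,
              genes_affected = affected, metagene = profiles,
              degs = degs, integration = integration,
              correlations = correlations, overlaps = overlaps,
              params = list(min_cov = min_cov, min_reps = min_reps,
                            dmc_fdr = dmc_fdr, dmr_window = dmr_window,
                            dmr_min_dmcs = dmr_min_dmcs,
                            dmr_min_diff = dmr_min_diff,
                            dmr_alpha = dmr_alpha, flank = flank,
                            min_cpm = min_cpm,
                            min_cpm_samples = min_cpm_samples,
                            deg_fdr = deg_fdr, min_fold = min_fold,
                            test = test, control = control))
  if (!is.null(output_dir)) write_pipeline_outputs(res, output_dir)
  res
}

#' Write the pipeline result bundle to disk
#'
#' @param res Result of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$conversion)) wt(res$conversion, "conversion_efficiency.tsv")
  write_dmc_table(res$dmc_table, file.path(dir, "dmc_table.tsv"))
  write_dmr_bed(res$dmrs, file.path(dir, "dmrs.bed"))
  if (nrow(res$dmc_assignments)) wt(res$dmc_assignments,
                                    "dmc_assignments.tsv")
  wt(res$genes_affected$dmc, "genes_affected_dmc.tsv")
  wt(res$genes_affected$dmr, "genes_affected_dmr.tsv")
  for (side in c("test", "control")) {
    if (nrow(res$metagene[[side]]))
      wt(res$metagene[[side]], paste0("metagene_", side, ".tsv"))
    write_bedgraph(res$tracks[[side]],
                   file.path(dir, paste0("track_", side)))
  }
  if (!is.null(res$degs)) wt(res$degs, "deg_table.tsv")
  if (!is.null(res$integration)) {
    wt(res$integration$records, "integration_records.tsv")
    wt(res$integration$genes, "integration_genes.tsv")
  }
  if (!is.null(res$correlations)) wt(res$correlations, "correlations.tsv")
  invisible(dir)
}

#' Planted-DMR recovery metrics
#'
#' Sensitivity is the fraction of planted intervals overlapped by at least
#' one called DMR; precision is the fraction of called DMRs overlapping a
#' planted interval.
#'
#' @param dmrs Called DMRs from [call_dmrs()].
#' @param truth_intervals Planted intervals (`chrom`, `start`, `end`).
#' @return Named numeric vector `sensitivity, precision`.
#' @export
dmr_recovery <- function(dmrs, truth_intervals) {
  overlaps <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i)
      any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end),
      logical(1))
  }
  sens <- if (nrow(truth_intervals)) mean(overlaps(truth_intervals, dmrs))
          else NA_real_
  prec <- if (nrow(dmrs)) mean(overlaps(dmrs, truth_intervals)) else NA_real_
  c(sensitivity = sens, precision = prec)
}

#' One-command synthetic end-to-end demonstration
#'
#' Simulates a dataset with planted truth, runs the full pipeline at the
#' default thresholds, and reports planted-truth recovery.
#'
#' @param seed Integer seed.
#' @param config A [sim_config()]; its seed is overridden by `seed`.
#' @param output_dir Optional output directory.
#' @return List: `data` (the simulated bundle), `result` (the pipeline
#'   bundle), `recovery` (DMR recovery metrics plus DEG recall/counts).
#' @export
run_demo <- function(seed = 1L, config = sim_config(), output_dir = NULL) {
  config$seed <- as.integer(seed)
  data <- simulate_dataset(config)
  res <- run_pipeline(data$mset, data$eset, data$genes,
                      genome = data$genome, output_dir = output_dir)
  called_degs <- res$degs$gene_id[res$degs$is_deg]
  true_degs <- names(data$truth$deg_log2fc)
  # coupled gene bodies carry planted methylation changes too; a DMR
  # called there is a true positive
  coupled_iv <- data$genes[data$genes$gene_id %in% data$truth$coupled_genes,
                           c("chrom", "start", "end")]
  truth_iv <- rbind(data$truth$dmr_intervals[, c("chrom", "start", "end")],
                    coupled_iv)
  recovery <- list(
    dmr = dmr_recovery(res$dmrs, truth_iv),
    deg_recall = if (length(true_degs))
      mean(true_degs %in% called_degs) else NA_real_,
    n_dmcs = sum(res$dmc_table$is_dmc), n_dmrs = nrow(res$dmrs),
    n_degs = length(called_degs))
  list(data = data, result = res, recovery = recovery)
}

#' Write / read a simulation config as key = value text
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, a
#'   [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  flat <- config
  flat$baseline_levels <- paste(names(config$baseline_levels),
                                config$baseline_levels,
                                sep = ":", collapse = ",")
  flat$conditions <- paste(config$conditions, collapse = ",")
  writeLines(paste(names(flat), unlist(flat), sep = " = "), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  if (!"seed" %in% names(vals)) stop("config file must set seed")
  bl <- strsplit(strsplit(vals[["baseline_levels"]], ",")[[1]], ":")
  num <- function(x) as.numeric(vals[[x]])
  sim_config(
    seed = as.integer(vals[["seed"]]), n_chroms = num("n_chroms"),
    chrom_length = num("chrom_length"),
    chloroplast_length = num("chloroplast_length"),
    n_genes = num("n_genes"), gene_length_mean = num("gene_length_mean"),
    n_replicates = num("n_replicates"), depth_mean = num("depth_mean"),
    conversion_efficiency = num("conversion_efficiency"),
    baseline_levels = stats::setNames(
      as.numeric(vapply(bl, `[`, character(1), 2L)),
      vapply(bl, `[`, character(1), 1L)),
    n_true_dmcs = num("n_true_dmcs"), dmc_effect = num("dmc_effect"),
    n_true_dmrs = num("n_true_dmrs"), dmr_width = num("dmr_width"),
    n_true_degs = num("n_true_degs"), deg_log2fc = num("deg_log2fc"),
    nb_dispersion = num("nb_dispersion"),
    expr_mean_log = num("expr_mean_log"),
    expr_sd_log = num("expr_sd_log"),
    coupling_fraction = num("coupling_fraction"),
    organ = vals[["organ"]],
    conditions = strsplit(vals[["conditions"]], ",")[[1]])
}
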