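#' Pipeline configuration
#'
#' Assembles stage toggles and stage parameters for
#' \code{\link{runPipeline}}. Every random stage derives its seed from
#' \code{seed}, and all seeds used are echoed into the report, so a run is
#' reproducible bit-for-bit (apart from timestamps) from its config.
#'
#' @param seed master seed.
#' @param generator a \code{\link{generatorConfig}} (rebuilt with
#'   \code{seed} when omitted).
#' @param stages named logical vector toggling \code{simulate},
#'   \code{spectra}, \code{signatures}, \code{enrichment},
#'   \code{transcriptome}.
#' @param k_range,n_restarts rank-selection controls.
#' @param control_multiplier matched controls per observed mutation.
#' @param n_perm permutations for the shared-downregulation test.
#' @param n_boot bootstrap draws for enrichment intervals.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipelineConfig <- function(seed = 1L, generator = NULL,
                           stages = c(simulate = TRUE, spectra = TRUE,
                                      signatures = TRUE, enrichment = TRUE,
                                      transcriptome = TRUE),
                           k_range = 1:4, n_restarts = 10L,
                           control_multiplier = 10L, n_perm = 1000L,
                           n_boot = 1000L) {
  if (is.null(generator)) generator <- generatorConfig(seed = seed)
  cfg <- list(seed = as.integer(seed), generator = generator, stages = stages,
              k_range = k_range, n_restarts = as.integer(n_restarts),
              control_multiplier = as.integer(control_multiplier),
              n_perm = as.integer(n_perm), n_boot = as.integer(n_boot))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return Character vector of problems, each naming the offending field;
#'   empty when the config is runnable.
#' @export
validateConfig <- function(config) {
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)
  if (!inherits(config, "pipeline_config")) return("config: not a pipeline_config")
  if (length(config$seed) != 1L || is.na(config$seed)) add("seed: must be a single integer")
  if (config$n_perm < 1L) add("n_perm: must be positive")
  if (config$n_boot < 1L) add("n_boot: must be positive")
  if (config$control_multiplier < 1L) add("control_multiplier: must be positive")
  if (config$n_restarts < 1L) add("n_restarts: must be positive")
  if (length(config$k_range) == 0L || any(config$k_range < 1L) ||
      any(config$k_range > 96L))
    add("k_range: must lie in [1, 96]")
  need <- c("simulate", "spectra", "signatures", "enrichment", "transcriptome")
  if (!all(need %in% names(config$stages)))
    add("stages: must name all of simulate/spectra/signatures/enrichment/transcriptome")
  g <- config$generator
  if (!inherits(g, "generator_config")) add("generator: not a generator_config")
  else {
    if (g$rate_a1 < 0 || g$rate_a2 < 0) add("generator rates: must be nonnegative")
    if (g$genome_length < 100L * g$n_genes)
      add("generator genome_length: must be at least 100 x n_genes")
  }
  problems
}

#' Run the integrated pipeline on a synthetic corpus
#'
#' Executes the enabled stages in dependency order -- synthesize a corpus,
#' build per-cell spectra, extract signatures and fit clock rates, run
#' matched-control enrichment and strand bias, and run the transcriptome
#' aging analyses -- writing per-stage TSVs and a machine-readable
#' \code{report.json} into \code{out_dir}.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param out_dir output directory.
#' @return The report, invisibly (also written as JSON).
#' @export
runPipeline <- function(config, out_dir) {
  problems <- validateConfig(config)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  on <- function(s) isTRUE(config$stages[[s]])
  report <- list(seed = config$seed, timestamp = format(Sys.time()))
  g <- config$generator

  sim <- NULL; mut <- NULL; expr <- NULL
  if (on("simulate")) {
    sim <- simulateGenome(g)
    mut <- simulateMutations(g, sim)
    expr <- simulateExpression(g, sim$genes)
    report$simulate <- list(n_genes = length(sim$genes),
                            n_cells_wgs = nrow(mut$truth$cells),
                            n_mutations = length(mut$catalog),
                            n_cells_rna = ncol(expr$sce))
  }

  spectra <- NULL
  if (on("spectra")) {
    if (is.null(mut)) stop("stage 'spectra' requires stage 'simulate'")
    bs <- buildSpectrum(mut$catalog, sim$genome, by = "cell_id")
    spectra <- bs$spectrum
    writeSpectrumTSV(rowSums(spectra), file.path(out_dir, "aggregate_spectrum.tsv"))
    report$spectra <- list(
      n_dropped = bs$n_dropped,
      cosine_to_sbs5like = cosineSim(rowSums(spectra), referenceSignature("SBS5like")))
  }

  if (on("signatures")) {
    if (is.null(spectra)) stop("stage 'signatures' requires stage 'spectra'")
    rk <- selectRank(spectra, config$k_range, config$n_restarts,
                     seed = config$seed)
    ss <- nmfDecompose(spectra, k = rk$k, n_restarts = config$n_restarts,
                       seed = config$seed)
    expo <- refitExposures(spectra, signatures(ss))
    cells <- mut$truth$cells
    ages <- cells$age[match(colnames(spectra), cells$cell_id)]
    total_fit <- burdenAgeRegression(colSums(spectra), ages)
    sig_fits <- lapply(seq_len(rk$k), function(i)
      burdenAgeRegression(expo[i, ], ages))
    names(sig_fits) <- rownames(expo)
    writeSpectrumTSV(signatures(ss), file.path(out_dir, "signatures.tsv"))
    write.table(data.frame(cell_id = colnames(expo), t(expo)),
                file.path(out_dir, "exposures.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$signatures <- list(
      selected_k = rk$k, rank_table = rk$table,
      stability = restartStability(ss),
      total_slope = total_fit$slope, total_r2 = total_fit$r_squared,
      per_signature = lapply(sig_fits, function(f)
        list(slope = f$slope, r_squared = f$r_squared, p = f$p_value)),
      cosine_to_fixture = c(
        A1 = cosineSim(signatures(ss)[, 1], g$sig_a1),
        A2 = if (rk$k >= 2) cosineSim(signatures(ss)[, 2], g$sig_a2) else NA))
  }

  if (on("enrichment")) {
    if (is.null(mut)) stop("stage 'enrichment' requires stage 'simulate'")
    ann <- annotateMutations(mut$catalog, sim$genes, sim$genome)
    ctrl <- sampleMatchedControls(ann, sim$mask, sim$genome,
                                  multiplier = config$control_multiplier,
                                  seed = config$seed + 10L)
    ctrl_ann <- annotateMutations(ctrl, sim$genes, sim$genome)
    qmap <- setNames(sim$genes$expr_quintile, sim$genes$gene_id)
    enr_gi <- mutationEnrichment(ann, ctrl_ann, "genic_vs_intergenic",
                                 n_boot = config$n_boot, seed = config$seed)
    enr_q <- mutationEnrichment(ann, ctrl_ann, "expression_quintiles",
                                quintile_map = qmap, n_boot = config$n_boot,
                                seed = config$seed)
    sb <- strandBias(ann, qmap)
    write.table(enr_q, file.path(out_dir, "enrichment_quintiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sb, file.path(out_dir, "strand_bias.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tc <- sb[sb$sub_class == "T>C" & sb$quantile == "all", ]
    report$enrichment <- list(
      genic_ratio = enr_gi$ratio[enr_gi$partition_label == "genic"],
      quintile_ratios = enr_q$ratio,
      tc_fraction_transcribed = tc$fraction_transcribed)
  }

  if (on("transcriptome")) {
    if (is.null(expr)) stop("stage 'transcriptome' requires stage 'simulate'")
    tx <- analyzeAgingTranscriptome(expr$sce, sim$genes, g,
                                 n_perm = config$n_perm,
                                 seed = config$seed + 20L)
    write.table(tx$de, file.path(out_dir, "differential_expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$transcriptome <- list(
      n_significant = sum(tx$de$significant),
      n_down = sum(tx$de$direction == "down"),
      shared_observed = tx$shared$observed,
      shared_p = tx$shared$p_value,
      hk_decile_slope = tx$decile$fit$slope,
      hk_decile_r2 = tx$decile$fit$r_squared)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(report)
}

#' Run the elderly-versus-adult transcriptome aging analyses
#'
#' Bundles the expression stages run per synthetic cell type: log
#' normalization, elderly-vs-adult differential expression, per-type
#' down-regulated and expressed gene sets, the cross-cell-type
#' shared-downregulation permutation test, and the housekeeping
#' length-decile fold-change trend (in excitatory cells).
#'
#' @param sce a \code{SingleCellExperiment} with \code{counts} and
#'   \code{cell_type}/\code{age_group} columns (e.g. from
#'   \code{\link{simulateExpression}}).
#' @param genes gene \code{GRanges} with \code{gene_class} and
#'   \code{gene_length}.
#' @param gcfg the \code{\link{generatorConfig}} (supplies the cell-type
#'   category map).
#' @param n_perm permutations for the shared-downregulation test.
#' @param seed integer seed.
#' @return List with \code{de} (all cell types), \code{down_sets},
#'   \code{expressed_sets}, \code{shared} (permutation result) and
#'   \code{decile} (housekeeping length-decile trend).
#' @export
analyzeAgingTranscriptome <- function(sce, genes, gcfg, n_perm = 1000L, seed = 1L) {
  norm <- logNormalize(SummarizedExperiment::assay(sce, "counts"))
  cd <- SummarizedExperiment::colData(sce)
  cts <- unique(cd$cell_type)
  de_list <- list(); down_sets <- list(); expr_sets <- list()
  for (ct in cts) {
    el <- rownames(cd)[cd$cell_type == ct & cd$age_group == "elderly"]
    ad <- rownames(cd)[cd$cell_type == ct & cd$age_group == "adult"]
    de <- differentialExpression(norm, el, ad)
    de$cell_type <- ct
    de_list[[ct]] <- de
    down_sets[[ct]] <- de$gene_id[de$significant & de$direction == "down"]
    expr_sets[[ct]] <- differentialExpression(
      norm, el, ad, pct_filter = "adult25_elderly20")$gene_id
    down_sets[[ct]] <- intersect(down_sets[[ct]], expr_sets[[ct]])
  }
  de_all <- do.call(rbind, de_list)
  shared <- sharedDownPermutation(down_sets, expr_sets,
                                  categories = gcfg$celltype_category,
                                  n_perm = n_perm, seed = seed)
  hk <- genes[genes$gene_class == "housekeeping"]
  de_ex <- de_list[["Ex"]]
  hk_de <- de_ex[de_ex$gene_id %in% hk$gene_id, ]
  hk_len <- setNames(hk$gene_length, hk$gene_id)
  decile <- lengthDecileFoldChange(hk_de$log2_fc, hk_len[hk_de$gene_id],
                                   hk_de$gene_id)
  list(de = de_all, down_sets = down_sets, expressed_sets = expr_sets,
       shared = shared, decile = decile)
}
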