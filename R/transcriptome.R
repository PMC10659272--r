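#' @importFrom stats wilcox.test fisher.test p.adjust pnorm
NULL

.getCounts <- function(x) {
  if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}

#' Log-normalize a gene x cell count matrix
#'
#' Per cell: \code{ln(1 + count * scale / cell_total)} with the conventional
#' scale factor of 10,000 -- the "logged CPM"-style quantity used throughout
#' the expression analyses.
#'
#' @param x counts matrix (genes x cells) or a \code{SummarizedExperiment}
#'   with a \code{counts} assay.
#' @param scale library scale factor.
#' @return Matrix of normalized values (same dimnames); for a
#'   \code{SingleCellExperiment} input the object is returned with a
#'   \code{logcounts} assay added.
#' @export
logNormalize <- function(x, scale = 10000) {
  counts <- .getCounts(x)
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("all-zero cell(s): ",
         paste(utils::head(colnames(counts)[tot == 0], 5L), collapse = ", "))
  norm <- log1p(sweep(counts, 2, scale / tot, "*"))
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "logcounts") <- norm
    x
  } else norm
}

#' Elderly-versus-adult differential expression per gene
#'
#' Genes passing a percent-expressed filter are tested by a two-sided
#' Wilcoxon rank-sum test on log-normalized values. The fold change is
#' \code{log2((mean(expm1(elderly)) + pseudocount) / (mean(expm1(adult)) +
#' pseudocount))}. A gene is flagged significant when \code{|log2FC| > lfc},
#' \code{p < alpha} and the filter holds; p-values are raw (an optional
#' BH-adjusted column is included for convenience but plays no role in the
#' significance call).
#'
#' Two named filter presets exist: \code{"either"} requires expression in at
#' least \code{min_pct} of elderly or adult cells (the differential
#' expression filter); \code{"adult25_elderly20"} requires expression in at
#' least 25\% of adult and 20\% of elderly cells (the "expressed gene"
#' definition used by the shared-downregulation permutation test).
#'
#' @param norm log-normalized matrix (genes x cells).
#' @param cells_elderly,cells_adult column names or indices of the two groups
#'   (each at least 3 cells).
#' @param min_pct percent-expressed threshold for the \code{"either"} preset.
#' @param lfc minimum absolute log2 fold change.
#' @param alpha p-value threshold.
#' @param pseudocount fold-change pseudocount.
#' @param pct_filter filter preset.
#' @return data.frame with \code{gene_id}, \code{log2_fc}, \code{p_value},
#'   \code{p_adj}, \code{pct_elderly}, \code{pct_adult}, \code{significant},
#'   \code{direction} (\code{up}/\code{down}/\code{none}); only genes passing
#'   the filter are returned.
#' @export
differentialExpression <- function(norm, cells_elderly, cells_adult,
                                   min_pct = 0.25, lfc = 0.5, alpha = 0.05,
                                   pseudocount = 1,
                                   pct_filter = c("either", "adult25_elderly20")) {
  pct_filter <- match.arg(pct_filter)
  if (is(norm, "SummarizedExperiment"))
    norm <- SummarizedExperiment::assay(norm, "logcounts")
  E <- norm[, cells_elderly, drop = FALSE]
  A <- norm[, cells_adult, drop = FALSE]
  if (ncol(E) < 3L || ncol(A) < 3L) stop("each group needs at least 3 cells")
  pct_e <- rowMeans(E > 0)
  pct_a <- rowMeans(A > 0)
  pass <- if (pct_filter == "either") pmax(pct_e, pct_a) >= min_pct
          else pct_a >= 0.25 & pct_e >= 0.20
  idx <- which(pass)
  p <- vapply(idx, function(g) {
    suppressWarnings(wilcox.test(E[g, ], A[g, ], exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  l2 <- log2((rowMeans(expm1(E[idx, , drop = FALSE])) + pseudocount) /
             (rowMeans(expm1(A[idx, , drop = FALSE])) + pseudocount))
  sig <- abs(l2) > lfc & p < alpha
  data.frame(gene_id = rownames(norm)[idx],
             log2_fc = as.numeric(l2), p_value = p,
             p_adj = p.adjust(p, "BH"),
             pct_elderly = pct_e[idx], pct_adult = pct_a[idx],
             significant = sig,
             direction = ifelse(!sig, "none", ifelse(l2 > 0, "up", "down")),
             row.names = NULL)
}

#' Classify genes as housekeeping, neuron-specific or other
#'
#' Operates on mean logged-CPM profiles over four reference cell types.
#' Housekeeping: the spread (max - min) of the four means is strictly below
#' 0.1 and every mean is strictly above 0.1. Neuron-specific: both neuron
#' means strictly above 0.2 and both microglia/endothelia means strictly
#' below 0.1. Everything else is \code{"other"}.
#'
#' @param means matrix (genes x 4) with columns \code{excitatory},
#'   \code{inhibitory}, \code{microglia}, \code{endothelia} (order is
#'   matched by name).
#' @param gene_ids optional gene identifiers (default rownames).
#' @return data.frame \code{gene_id}, \code{class}, plus the four means.
#' @export
classifyGenePrograms <- function(means, gene_ids = rownames(means)) {
  need <- c("excitatory", "inhibitory", "microglia", "endothelia")
  if (!all(need %in% colnames(means)))
    stop("means must have columns: ", paste(need, collapse = ", "))
  m <- as.matrix(means[, need, drop = FALSE])
  if (anyNA(m)) stop("missing cell-type mean(s)")
  spread <- apply(m, 1, max) - apply(m, 1, min)
  # strict < 0.1 with a guard so a spread of exactly 0.1 (up to representation
  # error) is excluded
  hk <- spread < 0.1 - 1e-9 & apply(m, 1, min) > 0.1
  ns <- m[, "excitatory"] > 0.2 & m[, "inhibitory"] > 0.2 &
        m[, "microglia"] < 0.1 & m[, "endothelia"] < 0.1
  cls <- ifelse(hk, "housekeeping", ifelse(ns, "neuron_specific", "other"))
  data.frame(gene_id = if (is.null(gene_ids)) seq_len(nrow(m)) else gene_ids,
             class = cls, m, row.names = NULL)
}

#' Permutation test for cross-cell-type shared downregulation
#'
#' The observed statistic is the number of genes downregulated in at least
#' one excitatory, at least one inhibitory and at least \code{min_glial}
#' glial cell types. Each permutation redraws, for every cell type, a
#' uniform random subset of its expressed genes of the same size as its
#' down-set and recomputes the statistic; the empirical p-value is
#' \code{(1 + #permutations >= observed) / (n_perm + 1)}.
#'
#' @param down_sets named list (per cell type) of downregulated gene ids;
#'   each must be a subset of the matching expressed set.
#' @param expressed_sets named list (per cell type) of expressed gene ids.
#' @param categories named character vector mapping each cell type to
#'   \code{"excitatory"}, \code{"inhibitory"}, \code{"glial"} or other.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param min_glial glial cell types required.
#' @return List with \code{observed}, \code{perm_counts}, \code{p_value}.
#' @export
sharedDownPermutation <- function(down_sets, expressed_sets, categories,
                                  n_perm = 1000L, seed = 1L, min_glial = 2L) {
  cts <- names(down_sets)
  if (!setequal(cts, names(expressed_sets)))
    stop("down_sets and expressed_sets must cover the same cell types")
  if (!all(cts %in% names(categories)))
    stop("categories missing for: ",
         paste(setdiff(cts, names(categories)), collapse = ", "))
  for (ct in cts)
    if (!all(down_sets[[ct]] %in% expressed_sets[[ct]]))
      stop("down set of ", ct, " is not a subset of its expressed set")
  catv <- categories[cts]
  if (!any(catv == "excitatory") || !any(catv == "inhibitory") ||
      sum(catv == "glial") < min_glial)
    stop("criterion needs excitatory, inhibitory and >= ", min_glial,
         " glial cell types among the inputs")
  count_shared <- function(sets) {
    genes <- unique(unlist(sets))
    if (!length(genes)) return(0L)
    inset <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
    inset <- matrix(inset, nrow = length(genes))
    nex <- rowSums(inset[, catv == "excitatory", drop = FALSE])
    nin <- rowSums(inset[, catv == "inhibitory", drop = FALSE])
    ngl <- rowSums(inset[, catv == "glial", drop = FALSE])
    sum(nex >= 1L & nin >= 1L & ngl >= min_glial)
  }
  observed <- count_shared(down_sets)
  set.seed(seed)
  perm_counts <- vapply(seq_len(n_perm), function(i) {
    count_shared(lapply(cts, function(ct)
      sample(expressed_sets[[ct]], length(down_sets[[ct]]))))
  }, integer(1))
  list(observed = observed, perm_counts = perm_counts,
       p_value = (1 + sum(perm_counts >= observed)) / (n_perm + 1))
}

#' Fisher's exact test for down-regulation enrichment of a gene set
#'
#' Two-sided Fisher's exact test on the 2x2 table (in set vs not) x
#' (down-regulated vs not), over a background of active genes.
#'
#' @param down_genes downregulated gene ids.
#' @param gene_set the gene set of interest (subset of background).
#' @param background active-gene background.
#' @return List with \code{odds_ratio}, \code{p_value}, \code{table}.
#' @export
geneSetEnrichment <- function(down_genes, gene_set, background) {
  if (!length(background)) stop("background must be nonempty")
  if (!all(gene_set %in% background)) stop("gene_set must be a subset of background")
  down_genes <- intersect(down_genes, background)
  inset <- background %in% gene_set
  isdown <- background %in% down_genes
  tab <- table(factor(inset, c(TRUE, FALSE)), factor(isdown, c(TRUE, FALSE)))
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Two-sided rank-sum test for a cell-type composition trend
#'
#' Compares per-donor cell-type fractions between two donor groups with a
#' two-sided Wilcoxon rank-sum test, exact when the combined sample is small
#' (n <= 20) and tie-free, normal approximation otherwise.
#'
#' @param fractions numeric per-donor fractions.
#' @param groups two-level factor/character of the same length.
#' @return List with \code{p_value}, \code{statistic}, \code{exact}.
#' @export
compositionTrend <- function(fractions, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  x <- fractions[groups == levels(groups)[1]]
  y <- fractions[groups == levels(groups)[2]]
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  exact <- (length(x) + length(y)) <= 20L && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  p <- wt$p.value
  if (is.nan(p)) p <- 1   # fully tied samples carry no evidence
  list(p_value = p, statistic = unname(wt$statistic), exact = exact)
}

#' Fold change across gene-length deciles
#'
#' Ranks genes by length into deciles (ties by identifier), summarizes the
#' per-decile median log2 fold change, and fits ordinary least squares of
#' the decile medians on the decile index.
#'
#' @param log2_fc per-gene log2 fold changes.
#' @param lengths per-gene lengths (bp).
#' @param gene_ids gene identifiers.
#' @param n_deciles number of length bins.
#' @return List with \code{table} (decile, n, median_log2_fc) and \code{fit}.
#' @export
lengthDecileFoldChange <- function(log2_fc, lengths, gene_ids, n_deciles = 10L) {
  stopifnot(length(log2_fc) == length(lengths), length(lengths) == length(gene_ids))
  d <- .decileByLength(lengths, gene_ids, n_deciles)
  f <- factor(d, levels = seq_len(n_deciles))
  tab <- data.frame(decile = seq_len(n_deciles),
                    n = as.integer(table(f)),
                    median_log2_fc = as.numeric(tapply(log2_fc, f, median)))
  fit <- burdenAgeRegression(tab$median_log2_fc, tab$decile)
  list(table = tab, fit = fit)
}

#' Compare two correlations by Fisher's r-to-z transformation
#'
#' Used to contrast the length/fold-change correlation of two gene classes
#' (e.g. housekeeping versus neuron-specific genes).
#'
#' @param r1,n1 correlation and sample size of the first fit.
#' @param r2,n2 correlation and sample size of the second fit.
#' @return List with \code{z} and the two-sided \code{p_value}.
#' @export
fisherRtoZ <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both groups")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}
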