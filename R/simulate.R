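#' @importFrom stats rpois rnbinom runif rlnorm setNames median quantile
NULL

#' Configuration for the synthetic aging-cortex generator
#'
#' Bundles every tunable of the synthetic corpus. The defaults are the study
#' conditions the downstream analyses assume: the 13 packaged donor ages
#' (infant to centenarian), 5 whole-genome-sequenced neurons per donor, and
#' two clock-like mutational processes accruing 13.8 and 1.8 sSNVs per
#' neuron per year (together 15.6/yr), shaped like the packaged SBS5-like
#' (T>C-weighted, flat-ish) and SBS30-like (C>T-dominant) signature vectors.
#'
#' Per-signature burdens are negative-binomial around the age trend. The
#' default dispersions (\code{disp_a1 = 50}, \code{disp_a2 = 1.4}) are chosen
#' so that at these ages the expected coefficients of determination of the
#' per-cell burden-on-age regressions are about 0.94 for the T>C-dominant
#' component and about 0.90 for the total, with wide per-cell scatter in the
#' C>T-dominant component -- the extra-Poisson behavior single-neuron aging
#' data show. Set both to \code{Inf} for pure Poisson burdens.
#'
#' Placement: within each trinucleotide stratum, component-1 mutations favor
#' genic sites with a weight increasing over expression quintiles
#' (\code{genic_weight_by_quintile}), component-2 mutations favor intergenic
#' sites (\code{a2_intergenic_weight}); genic T>C mutations fall with
#' probability \code{strand_asymmetry} on sites whose pyrimidine lies on the
#' gene's template strand (transcription-coupled-repair-style bias). Because
#' the weighting acts within strata, the 96-context mixture of the catalog is
#' the configured signature mixture regardless of placement weights.
#'
#' Expression: negative-binomial counts for 6 synthetic cell types
#' (excitatory and inhibitory neurons, oligodendrocyte, astrocyte, microglia,
#' endothelia). In elderly cells, housekeeping genes decline with a planted
#' log2 fold change interpolated from \code{hk_decline_max} at the shortest
#' length decile to 0 at the longest; neuron-specific genes are stable; a
#' planted module of \code{shared_down_genes} well-expressed genes is
#' downregulated by \code{shared_down_lfc} in one excitatory, one inhibitory
#' and two glial cell types.
#'
#' @param seed integer seed; all randomness in the generator flows from it.
#' @param donor_ages donor ages in years (default: the packaged 13-donor table).
#' @param cells_per_donor scWGS neurons simulated per donor.
#' @param rate_a1,rate_a2 per-year mutation rates of the two components.
#' @param intercept_a1,intercept_a2 expected burden of each component already
#'   present at age 0 (birth-acquired mutations). The default places a small
#'   C>T-dominant load at birth, so infant neurons are dominated by the
#'   second component while aged neurons are dominated by the first -- the
#'   across-age variation in signature mix that makes a two-component
#'   factorization identifiable.
#' @param disp_a1,disp_a2 negative-binomial size of per-cell burdens
#'   (\code{Inf} = Poisson).
#' @param sig_a1,sig_a2 96-vector context probabilities of the two components.
#' @param genome_length,n_genes toy genome size (bp) and gene count.
#' @param genic_weight_by_quintile 5 increasing placement weights for
#'   component-1 mutations in genes of expression quintiles 1-5.
#' @param a2_intergenic_weight intergenic placement weight (> 1) for
#'   component-2 mutations.
#' @param strand_asymmetry in [0.5, 1]: fraction of genic T>C mutations whose
#'   pyrimidine lies on the template strand.
#' @param hk_decline_max planted log2FC of the shortest housekeeping decile
#'   in elderly cells (0 disables the decline).
#' @param shared_down_genes,shared_down_lfc size and planted log2FC of the
#'   shared downregulated module.
#' @param cells_per_type_per_donor snRNA-seq cells per donor per cell type.
#' @param nb_size_expr negative-binomial size of expression counts.
#' @param target_libsize nominal per-cell total count.
#' @return A list of class \code{"generator_config"}.
#' @export
generatorConfig <- function(seed = 1L,
                            donor_ages = NULL,
                            cells_per_donor = 5L,
                            rate_a1 = 13.8, rate_a2 = 1.8,
                            intercept_a1 = 0, intercept_a2 = 25,
                            disp_a1 = 50, disp_a2 = 1.4,
                            sig_a1 = NULL, sig_a2 = NULL,
                            genome_length = 2000000L, n_genes = 1000L,
                            genic_weight_by_quintile = c(1, 1.5, 2.2, 3.2, 4.5),
                            a2_intergenic_weight = 2,
                            strand_asymmetry = 0.65,
                            hk_decline_max = -1,
                            shared_down_genes = 30L, shared_down_lfc = -1.5,
                            cells_per_type_per_donor = 20L,
                            nb_size_expr = 2,
                            target_libsize = 5000) {
  if (is.null(donor_ages)) donor_ages <- donorTable()$age_years
  if (is.null(sig_a1)) sig_a1 <- referenceSignature("SBS5like")
  if (is.null(sig_a2)) sig_a2 <- referenceSignature("SBS30like")
  stopifnot(length(sig_a1) == 96L, length(sig_a2) == 96L,
            all(sig_a1 >= 0), all(sig_a2 >= 0),
            abs(sum(sig_a1) - 1) < 1e-6, abs(sum(sig_a2) - 1) < 1e-6,
            all(genic_weight_by_quintile > 0), a2_intergenic_weight > 0,
            strand_asymmetry >= 0.5, strand_asymmetry <= 1,
            rate_a1 >= 0, rate_a2 >= 0, intercept_a1 >= 0, intercept_a2 >= 0)
  cfg <- list(seed = as.integer(seed), donor_ages = donor_ages,
              cells_per_donor = as.integer(cells_per_donor),
              rate_a1 = rate_a1, rate_a2 = rate_a2,
              intercept_a1 = intercept_a1, intercept_a2 = intercept_a2,
              disp_a1 = disp_a1, disp_a2 = disp_a2,
              sig_a1 = unname(sig_a1), sig_a2 = unname(sig_a2),
              genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              genic_weight_by_quintile = genic_weight_by_quintile,
              a2_intergenic_weight = a2_intergenic_weight,
              strand_asymmetry = strand_asymmetry,
              hk_decline_max = hk_decline_max,
              shared_down_genes = as.integer(shared_down_genes),
              shared_down_lfc = shared_down_lfc,
              cells_per_type_per_donor = as.integer(cells_per_type_per_donor),
              nb_size_expr = nb_size_expr,
              target_libsize = target_libsize,
              celltypes = c("Ex", "In", "Oli", "Ast", "Mic", "End"),
              celltype_category = c(Ex = "excitatory", In = "inhibitory",
                                    Oli = "glial", Ast = "glial", Mic = "glial",
                                    End = "endothelial"))
  class(cfg) <- "generator_config"
  cfg
}

.ageGroup <- function(age) {
  ifelse(age < 1, "infant", ifelse(age >= 82, "elderly", "adult"))
}

.donorFrame <- function(config) {
  data.frame(donor_id = sprintf("sd%02d", seq_along(config$donor_ages)),
             age = config$donor_ages,
             group = .ageGroup(config$donor_ages),
             stringsAsFactors = FALSE)
}

.rcounts <- function(n, mu, size) {
  if (is.infinite(size)) rpois(n, mu) else rnbinom(n, mu = mu, size = size)
}

#' Generate a toy genome with annotated genes and a callable mask
#'
#' Builds an i.i.d.-uniform reference sequence, packs non-overlapping genes
#' with log-normal lengths onto it, labels each gene housekeeping /
#' neuron-specific / other, assigns per-cell-type mean expression levels
#' (mean logged CPM scale) that satisfy the gene-program classification
#' thresholds by construction, and derives a callable mask covering the
#' genome minus a few random dropout windows. Neuron-specific genes are drawn
#' longer on average than housekeeping genes, as in cortical annotation.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return List with \code{genome} (\code{DNAStringSet}, one chromosome
#'   \code{"chrS"}), \code{genes} (\code{GRanges} with \code{gene_id},
#'   \code{gene_class}, \code{gene_length}, \code{expr_mean} matrix and
#'   \code{expr_quintile}), and \code{mask} (\code{GRanges}).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$genome_length < 100L * config$n_genes)
    stop("genome_length must be at least 100 x n_genes")
  set.seed(config$seed)
  L <- config$genome_length
  n <- config$n_genes
  seq <- paste(sample(.BASES, L, replace = TRUE), collapse = "")
  genome <- DNAStringSet(setNames(seq, "chrS"))

  n_hk <- round(0.3 * n); n_ns <- round(0.2 * n)
  cls <- sample(c(rep("housekeeping", n_hk), rep("neuron_specific", n_ns),
                  rep("other", n - n_hk - n_ns)))
  len <- integer(n)
  len[cls == "housekeeping"] <- pmax(60L, round(rlnorm(sum(cls == "housekeeping"), log(400), 0.4)))
  len[cls == "neuron_specific"] <- pmax(60L, round(rlnorm(sum(cls == "neuron_specific"), log(900), 0.4)))
  len[cls == "other"] <- pmax(60L, round(rlnorm(sum(cls == "other"), log(600), 0.5)))
  total_gap <- L - sum(len) - 2L * (n + 1L)
  if (total_gap < 0)
    stop("gene packing infeasible: increase genome_length or reduce n_genes")
  g <- diff(c(0, sort(runif(n)), 1))
  gaps <- floor(g * total_gap) + 2L          # n + 1 gaps, min 2 bp for flanks
  starts <- cumsum(c(gaps[1], len[-n] + gaps[2:n])) + 1L
  genes <- GRanges("chrS", IRanges(starts, width = len),
                   strand = sample(c("+", "-"), n, replace = TRUE))
  if (max(end(genes)) > L - 1L)
    stop("gene packing infeasible: increase genome_length")

  ct <- config$celltypes
  em <- matrix(0, n, length(ct), dimnames = list(NULL, ct))
  hk <- which(cls == "housekeeping")
  em[hk, ] <- runif(length(hk), 0.3, 2.0)          # identical across types
  ns <- which(cls == "neuron_specific")
  em[ns, c("Ex", "In")] <- runif(2 * length(ns), 0.3, 1.5)
  em[ns, c("Oli", "Ast")] <- runif(2 * length(ns), 0, 0.08)
  em[ns, c("Mic", "End")] <- runif(2 * length(ns), 0, 0.05)
  oth <- which(cls == "other")
  four_ix <- match(c("Ex", "In", "Mic", "End"), ct)
  for (i in oth) {
    repeat {                       # redraw draws that collide with a class rule
      v <- runif(length(ct), 0, 1.2)
      four <- v[four_ix]
      is_hk <- (max(four) - min(four) < 0.1) && all(four > 0.1)
      is_ns <- all(four[1:2] > 0.2) && all(four[3:4] < 0.1)
      if (!is_hk && !is_ns) break
    }
    em[i, ] <- v
  }

  mcols(genes) <- DataFrame(gene_id = sprintf("g%04d", seq_len(n)),
                            gene_class = cls, gene_length = len)
  mcols(genes)$expr_mean <- em
  mcols(genes)$expr_quintile <- expressionQuintiles(em[, "Ex"], genes$gene_id)

  drop_n <- 20L
  drop_start <- sort(sample.int(L - 2000L, drop_n))
  dropped <- IRanges::reduce(GRanges("chrS", IRanges(drop_start, width = 2000L)))
  mask <- GenomicRanges::setdiff(GRanges("chrS", IRanges(2L, L - 1L)), dropped)
  list(genome = genome, genes = genes, mask = mask)
}

# index every maskable position by its canonical trinucleotide stratum.
# Returns a data.frame: pos, chrom, tri (1-32), pyr_plus, and when `genes`
# is supplied: gene (index or NA), quintile, on_template.
.siteTable <- function(genome, mask, genes = NULL) {
  out <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    ch <- names(genome)[ci]
    s <- genome[[ch]]
    L <- length(s)
    map <- integer(128L)
    map[utf8ToInt("A")] <- 1L; map[utf8ToInt("C")] <- 2L
    map[utf8ToInt("G")] <- 3L; map[utf8ToInt("T")] <- 4L
    codes <- map[utf8ToInt(as.character(s))]
    p <- 2:(L - 1L)
    ctr <- codes[p]; lf <- codes[p - 1L]; rt <- codes[p + 1L]
    ok <- ctr > 0L & lf > 0L & rt > 0L
    mir <- mask[seqnames(mask) == ch]
    inmask <- IRanges::overlapsAny(IRanges(p, p), IRanges::ranges(mir))
    keep <- which(ok & inmask)
    ctr <- ctr[keep]; lf <- lf[keep]; rt <- rt[keep]; p <- p[keep]
    pyr_plus <- ctr == 2L | ctr == 4L
    c_ctr <- ifelse(pyr_plus, ctr, 5L - ctr)
    c_lf <- ifelse(pyr_plus, lf, 5L - rt)
    c_rt <- ifelse(pyr_plus, rt, 5L - lf)
    tri <- (c_ctr == 4L) * 16L + (c_lf - 1L) * 4L + c_rt
    out[[ci]] <- data.frame(pos = p, chrom = ch, tri = as.integer(tri),
                            pyr_plus = pyr_plus, stringsAsFactors = FALSE)
  }
  st <- do.call(rbind, out)
  if (!is.null(genes)) {
    posgr <- GRanges(st$chrom, IRanges(st$pos, st$pos))
    hit <- findOverlaps(posgr, genes, select = "first")
    st$gene <- hit
    st$quintile <- ifelse(is.na(hit), NA_integer_, genes$expr_quintile[hit])
    gene_plus <- as.character(strand(genes)) == "+"
    st$on_template <- ifelse(is.na(hit), NA, gene_plus[hit] != st$pyr_plus)
  }
  st
}

#' Simulate per-cell somatic SNV catalogs
#'
#' Draws per-cell burdens for the two mutational components around their
#' configured per-year clock rates, assigns each mutation a 96-context from
#' the corresponding signature, and places it on a callable site carrying
#' that exact trinucleotide, re-weighted by expression quintile (component
#' 1), intergenic preference (component 2) and template-strand asymmetry
#' (genic T>C). See \code{\link{generatorConfig}} for the model.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param genome_obj result of \code{\link{simulateGenome}}.
#' @param sites optional precomputed site table from a previous call on the
#'   same genome (returned in \code{$sites}); reusing it speeds up replicate
#'   catalogs over one reference.
#' @return List with \code{catalog} (a \linkS4class{MutationCatalog}),
#'   and \code{truth}: \code{cells} (cell_id, donor_id, age, n_a1, n_a2),
#'   \code{mutation_signature} (per-mutation component label aligned with the
#'   catalog), and the configured rates; and \code{sites} (the reusable
#'   site table).
#' @export
simulateMutations <- function(config, genome_obj, sites = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  donors <- .donorFrame(config)
  cells <- do.call(rbind, lapply(seq_len(nrow(donors)), function(i) {
    data.frame(cell_id = sprintf("%s_c%02d", donors$donor_id[i],
                                 seq_len(config$cells_per_donor)),
               donor_id = donors$donor_id[i], age = donors$age[i],
               stringsAsFactors = FALSE)
  }))
  nc <- nrow(cells)
  n_a1 <- .rcounts(nc, config$intercept_a1 + config$rate_a1 * cells$age, config$disp_a1)
  n_a2 <- .rcounts(nc, config$intercept_a2 + config$rate_a2 * cells$age, config$disp_a2)
  cells$n_a1 <- n_a1; cells$n_a2 <- n_a2

  total <- sum(n_a1) + sum(n_a2)
  if (total == 0L) {
    truth <- list(cells = cells, mutation_signature = character(),
                  rate_a1 = config$rate_a1, rate_a2 = config$rate_a2)
    return(list(catalog = MutationCatalog(), truth = truth, sites = sites))
  }
  cell_of <- c(rep(seq_len(nc), n_a1), rep(seq_len(nc), n_a2))
  sig_of <- c(rep(1L, sum(n_a1)), rep(2L, sum(n_a2)))
  ctx <- integer(total)
  i1 <- sig_of == 1L
  ctx[i1] <- sample.int(96L, sum(i1), replace = TRUE, prob = config$sig_a1)
  ctx[!i1] <- sample.int(96L, sum(!i1), replace = TRUE, prob = config$sig_a2)

  st <- if (is.null(sites)) .siteTable(genome_obj$genome, genome_obj$mask, genome_obj$genes) else sites
  tri_of <- .contextToTri(ctx)
  cls_of <- contextClassIndex()[ctx]
  is_tc <- cls_of == "T>C"
  site_row <- integer(total)
  qw <- config$genic_weight_by_quintile
  beta <- config$strand_asymmetry
  groups <- split(seq_len(total),
                  list(tri = factor(tri_of, levels = 1:32),
                       sig = factor(sig_of, levels = 1:2),
                       tc = factor(is_tc, levels = c(FALSE, TRUE))),
                  drop = TRUE)
  tri_index <- split(seq_len(nrow(st)), factor(st$tri, levels = 1:32))
  for (g in groups) {
    tri <- tri_of[g[1]]; sg <- sig_of[g[1]]; tc <- is_tc[g[1]]
    rows <- tri_index[[tri]]
    if (length(rows) == 0L)
      stop("trinucleotide context ", .triLabels()[tri],
           " absent from the callable reference")
    genic <- !is.na(st$gene[rows])
    w <- numeric(length(rows))
    if (sg == 1L) {
      w[genic] <- qw[st$quintile[rows[genic]]]
      w[!genic] <- 1
    } else {
      w[genic] <- 1
      w[!genic] <- config$a2_intergenic_weight
    }
    if (tc) {
      tmpl <- st$on_template[rows]
      w[genic] <- w[genic] * ifelse(tmpl[genic], 2 * beta, 2 * (1 - beta))
    }
    site_row[g] <- rows[sample.int(length(rows), length(g), replace = TRUE, prob = w)]
  }

  si <- (ctx - 1L) %/% 16L + 1L
  can_ref <- ifelse(si <= 3L, "C", "T")
  can_alt <- substr(.SUBS[si], 3L, 3L)
  pyr_plus <- st$pyr_plus[site_row]
  ref <- ifelse(pyr_plus, can_ref, .COMP[can_ref])
  alt <- ifelse(pyr_plus, can_alt, .COMP[can_alt])
  ord <- order(cell_of, st$chrom[site_row], st$pos[site_row])
  catalog <- MutationCatalog(st$chrom[site_row][ord], st$pos[site_row][ord],
                             unname(ref[ord]), unname(alt[ord]),
                             cells$cell_id[cell_of[ord]],
                             cells$donor_id[cell_of[ord]])
  truth <- list(cells = cells,
                mutation_signature = c("A1", "A2")[sig_of[ord]],
                rate_a1 = config$rate_a1, rate_a2 = config$rate_a2)
  list(catalog = catalog, truth = truth, sites = st)
}

#' Simulate a single-nucleus expression corpus with planted age effects
#'
#' Negative-binomial counts for 6 synthetic cell types across the configured
#' donors. In elderly cells, housekeeping genes carry a planted log2 fold
#' change interpolated from \code{hk_decline_max} (shortest length decile) to
#' 0 (longest); neuron-specific genes are unchanged; a planted module of
#' well-expressed genes is downregulated in one excitatory, one inhibitory
#' and two glial cell types. Every planted effect is recorded in the truth.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param genes the \code{genes} GRanges from \code{\link{simulateGenome}}.
#' @return List with \code{sce} (a \code{SingleCellExperiment} with a
#'   \code{counts} assay and \code{cell_type}, \code{donor_id},
#'   \code{age_group} in \code{colData}) and \code{truth} (planted log2FC
#'   matrix gene x cell type, housekeeping decile log2FCs, shared gene ids
#'   and cell types, baseline mean matrix).
#' @export
simulateExpression <- function(config, genes) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 2L)
  ct <- config$celltypes
  n <- length(genes)
  em <- mcols(genes)$expr_mean
  cls <- genes$gene_class

  hk <- which(cls == "housekeeping")
  if (length(hk) < 10L) stop("fewer housekeeping genes than length deciles")
  dec <- .decileByLength(genes$gene_length[hk], genes$gene_id[hk], 10L)
  hk_dec_lfc <- config$hk_decline_max * (10 - seq_len(10)) / 9
  hk_lfc <- setNames(hk_dec_lfc[dec], genes$gene_id[hk])

  oth <- which(cls == "other")
  shared <- sort(sample(oth, config$shared_down_genes))
  em[shared, ] <- matrix(runif(length(shared) * length(ct), 1.3, 1.8),
                         ncol = length(ct))
  shared_ct <- c("Ex", "In", "Oli", "Ast")

  lfc <- matrix(0, n, length(ct), dimnames = list(genes$gene_id, ct))
  lfc[hk, ] <- hk_lfc                         # decline in every cell type
  lfc[shared, shared_ct] <- lfc[shared, shared_ct] + config$shared_down_lfc

  donors <- .donorFrame(config)
  mu0 <- config$target_libsize * (exp(em) - 1) / 1e4   # per-gene per-type mean count
  ncpt <- config$cells_per_type_per_donor
  cols <- list(); mats <- list()
  for (ti in seq_along(ct)) {
    for (di in seq_len(nrow(donors))) {
      mu <- mu0[, ti]
      if (donors$group[di] == "elderly") mu <- mu * 2^lfc[, ti]
      libscale <- exp(stats::rnorm(ncpt, 0, 0.1))
      m <- matrix(.rcounts(n * ncpt, mu = rep(mu, ncpt) * rep(libscale, each = n),
                           size = config$nb_size_expr), nrow = n)
      mats[[length(mats) + 1L]] <- m
      cols[[length(cols) + 1L]] <- data.frame(
        cell_id = sprintf("%s_%s_n%02d", donors$donor_id[di], ct[ti], seq_len(ncpt)),
        cell_type = ct[ti], donor_id = donors$donor_id[di],
        age_group = donors$group[di], stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, mats)
  meta <- do.call(rbind, cols)
  dimnames(counts) <- list(genes$gene_id, meta$cell_id)
  storage.mode(counts) <- "integer"
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = DataFrame(cell_type = meta$cell_type, donor_id = meta$donor_id,
                        age_group = meta$age_group, row.names = meta$cell_id))
  truth <- list(planted_lfc = lfc,
                hk_decile_lfc = hk_dec_lfc,
                hk_lfc = hk_lfc,
                shared_genes = genes$gene_id[shared],
                shared_celltypes = shared_ct,
                baseline_mean = em)
  list(sce = sce, truth = truth)
}

#' Write a synthetic corpus to disk in standard formats
#'
#' Serializes a simulated corpus the same way real data would arrive:
#' reference FASTA, gene GFF3, callable-mask BED, one VCF per cell plus a
#' manifest TSV, a counts TSV with a cell-metadata TSV, and the truth record
#' as JSON.
#'
#' @param genome_obj result of \code{\link{simulateGenome}}.
#' @param mut result of \code{\link{simulateMutations}} (or NULL to skip).
#' @param expr result of \code{\link{simulateExpression}} (or NULL to skip).
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSyntheticCorpus <- function(genome_obj, mut = NULL, expr = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeXStringSet(genome_obj$genome, file.path(dir, "genome.fa"))
  genes <- genome_obj$genes
  gff <- granges(genes)
  mcols(gff) <- DataFrame(source = "scSomaAging", type = "gene",
                          ID = genes$gene_id, gene_class = genes$gene_class)
  rtracklayer::export(gff, file.path(dir, "genes.gff3"), format = "GFF3")
  rtracklayer::export(genome_obj$mask, file.path(dir, "callable_mask.bed"),
                      format = "BED")
  if (!is.null(mut)) {
    cat <- mut$catalog
    vdir <- file.path(dir, "vcf")
    dir.create(vdir, showWarnings = FALSE)
    cells <- mut$truth$cells
    for (i in seq_len(nrow(cells))) {
      sub <- cat[cat$cell_id == cells$cell_id[i]]
      writeMutationVCF(sub, file.path(vdir, paste0(cells$cell_id[i], ".vcf")))
    }
    write.table(data.frame(cell_id = cells$cell_id, donor_id = cells$donor_id,
                           path = file.path("vcf", paste0(cells$cell_id, ".vcf"))),
                file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(mut$truth$cells, file.path(dir, "mutation_truth.json"))
  }
  if (!is.null(expr)) {
    counts <- SummarizedExperiment::assay(expr$sce, "counts")
    write.table(data.frame(gene_id = rownames(counts), counts, check.names = FALSE),
                file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(expr$sce))
    write.table(data.frame(cell_id = rownames(cd), cd),
                file.path(dir, "cell_metadata.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(dir)
}

# length-decile assignment shared by several analyses (ties by identifier)
.decileByLength <- function(lengths, ids, n_deciles) {
  if (length(lengths) < n_deciles)
    stop("need at least ", n_deciles, " genes for decile analysis")
  ord <- order(lengths, ids)
  d <- integer(length(lengths))
  d[ord] <- ceiling(n_deciles * seq_along(ord) / length(ord))
  d
}
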