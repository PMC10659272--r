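#' @importFrom stats binom.test quantile
NULL

#' Annotate mutations with context, gene, region and transcriptional strand
#'
#' Computes each mutation's canonical 96-context, whether it falls in a gene,
#' and -- for genic mutations -- whether the pyrimidine of the canonical
#' context lies on the gene's template (transcribed) strand. A mutation whose
#' canonical pyrimidine sits on the coding strand is recorded as
#' \code{"untranscribed"}; on the template strand as \code{"transcribed"}.
#' A mutation overlapping several genes is assigned to the single gene for
#' which it is template-stranded if that gene is unique, otherwise to the
#' longest overlapping gene.
#'
#' @param x a \linkS4class{MutationCatalog}.
#' @param genes a \code{GRanges} of gene models (\code{gene_id} column).
#' @param genome named \code{DNAStringSet} or FASTA path.
#' @return The catalog with added columns \code{context}, \code{context_idx},
#'   \code{sub_class}, \code{complemented}, \code{gene_id} (NA when
#'   intergenic), \code{region} and \code{tx_strand}.
#' @export
annotateMutations <- function(x, genes, genome) {
  bs <- buildSpectrum(x, genome)
  ann <- bs$annotated
  if (length(ann) == 0L) return(ann)
  hits <- findOverlaps(granges(ann), genes)
  gene_of <- rep(NA_integer_, length(ann))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    pyr_plus <- !ann$complemented
    gene_plus <- as.character(strand(genes)) == "+"
    on_template <- gene_plus[s] != pyr_plus[q]
    for (qi in unique(q)) {
      cand <- s[q == qi]
      if (length(cand) == 1L) { gene_of[qi] <- cand; next }
      tmpl <- cand[on_template[q == qi]]
      gene_of[qi] <- if (length(tmpl) == 1L) tmpl
                     else cand[which.max(width(genes)[cand])]
    }
  }
  genic <- !is.na(gene_of)
  mcols(ann)$gene_id <- ifelse(genic, genes$gene_id[gene_of], NA_character_)
  mcols(ann)$region <- ifelse(genic, "genic", "intergenic")
  tx <- rep("not_applicable", length(ann))
  if (any(genic)) {
    gp <- as.character(strand(genes))[gene_of[genic]] == "+"
    pyr_plus <- !ann$complemented[genic]
    tx[genic] <- ifelse(gp != pyr_plus, "transcribed", "untranscribed")
  }
  mcols(ann)$tx_strand <- tx
  ann
}

#' Draw spectrum-matched random control positions
#'
#' For each observed mutation, draws \code{multiplier} control positions
#' uniformly among callable sites carrying the mutation's exact canonical
#' trinucleotide (on either strand) and assigns the same canonical
#' substitution, so the control 96-spectrum equals \code{multiplier} times
#' the observed spectrum exactly.
#'
#' @param annotated an annotated \linkS4class{MutationCatalog} (needs the
#'   \code{context_idx} column from \code{\link{annotateMutations}} or
#'   \code{\link{buildSpectrum}}).
#' @param mask \code{GRanges} of callable regions.
#' @param genome named \code{DNAStringSet} or FASTA path.
#' @param multiplier controls per observed mutation.
#' @param seed integer seed.
#' @return A \linkS4class{MutationCatalog} of control positions (cell and
#'   donor ids copied from the source mutations).
#' @export
sampleMatchedControls <- function(annotated, mask, genome, multiplier = 10L,
                                  seed = 1L) {
  if (length(annotated) == 0L) return(MutationCatalog())
  if (is.null(annotated$context_idx))
    stop("catalog must be annotated (run annotateMutations or buildSpectrum first)")
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  set.seed(seed)
  st <- .siteTable(genome, mask)
  tri_index <- split(seq_len(nrow(st)), factor(st$tri, levels = 1:32))
  ctx <- annotated$context_idx
  tri <- .contextToTri(ctx)
  need <- unique(tri)
  missing <- need[vapply(need, function(t) length(tri_index[[t]]) == 0L, logical(1))]
  if (length(missing))
    stop("no callable sites for trinucleotide context(s): ",
         paste(.triLabels()[missing], collapse = ", "))
  n <- length(annotated)
  src <- rep(seq_len(n), each = multiplier)
  rows <- integer(n * multiplier)
  for (t in need) {
    sel <- which(tri[src] == t)
    rows[sel] <- tri_index[[t]][sample.int(length(tri_index[[t]]), length(sel),
                                           replace = TRUE)]
  }
  si <- (ctx[src] - 1L) %/% 16L + 1L
  can_ref <- ifelse(si <= 3L, "C", "T")
  can_alt <- substr(.SUBS[si], 3L, 3L)
  pyr_plus <- st$pyr_plus[rows]
  MutationCatalog(st$chrom[rows], st$pos[rows],
                  unname(ifelse(pyr_plus, can_ref, .COMP[can_ref])),
                  unname(ifelse(pyr_plus, can_alt, .COMP[can_alt])),
                  annotated$cell_id[src], annotated$donor_id[src])
}

#' Enrichment of mutations over matched controls by genomic partition
#'
#' For each class of the partition (genic vs intergenic, or expression
#' quintiles 1-5 with intergenic excluded), computes the ratio of the
#' observed fraction to the control fraction, with a bootstrap confidence
#' interval obtained by resampling observed mutations. When a fixed
#' signature matrix is supplied, per-signature ratios are also computed by
#' splitting mutations via their per-context signature responsibilities
#' (soft, fractional by default; \code{attribution = "hard"} assigns each
#' mutation to its maximum-responsibility signature).
#'
#' @param observed,controls annotated \linkS4class{MutationCatalog}s (from
#'   \code{\link{annotateMutations}}).
#' @param partition \code{"genic_vs_intergenic"} or
#'   \code{"expression_quintiles"}.
#' @param quintile_map named integer vector gene_id -> quintile (required for
#'   the quintile partition), from \code{\link{expressionQuintiles}}.
#' @param n_boot bootstrap draws for the confidence interval.
#' @param conf confidence level.
#' @param seed integer seed.
#' @param signatures optional 96 x k column-stochastic matrix.
#' @param sig_weights optional prior mixing weights for responsibilities
#'   (default equal).
#' @param attribution \code{"soft"} or \code{"hard"}.
#' @return data.frame with one row per partition class: observed, expected
#'   (controls scaled to the observed total), ratio, ci_low, ci_high, and
#'   per-signature ratio columns when signatures are given.
#' @export
mutationEnrichment <- function(observed, controls,
                               partition = c("genic_vs_intergenic",
                                             "expression_quintiles"),
                               quintile_map = NULL, n_boot = 1000L,
                               conf = 0.95, seed = 1L,
                               signatures = NULL, sig_weights = NULL,
                               attribution = c("soft", "hard")) {
  partition <- match.arg(partition)
  attribution <- match.arg(attribution)
  lab <- function(x) {
    if (partition == "genic_vs_intergenic") x$region
    else {
      if (is.null(quintile_map)) stop("quintile_map required for expression_quintiles")
      ifelse(x$region == "genic", as.character(quintile_map[x$gene_id]), NA)
    }
  }
  ol <- lab(observed); cl <- lab(controls)
  keep_o <- !is.na(ol); keep_c <- !is.na(cl)
  ol <- ol[keep_o]; cl <- cl[keep_c]
  classes <- if (partition == "genic_vs_intergenic") c("genic", "intergenic")
             else as.character(1:5)
  ctab <- table(factor(cl, levels = classes))
  if (any(ctab == 0)) stop("empty partition class in controls: ",
                           paste(classes[ctab == 0], collapse = ", "))
  otab <- table(factor(ol, levels = classes))
  ratio <- as.numeric((otab / sum(otab)) / (ctab / sum(ctab)))
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, length(classes))
  fo <- factor(ol, levels = classes)
  for (b in seq_len(n_boot)) {
    bt <- table(fo[sample.int(length(fo), replace = TRUE)])
    boots[b, ] <- as.numeric((bt / sum(bt)) / (ctab / sum(ctab)))
  }
  alpha <- (1 - conf) / 2
  out <- data.frame(partition_label = classes,
                    observed = as.integer(otab),
                    expected = as.numeric(ctab) * sum(otab) / sum(ctab),
                    ratio = ratio,
                    ci_low = apply(boots, 2, quantile, alpha, na.rm = TRUE),
                    ci_high = apply(boots, 2, quantile, 1 - alpha, na.rm = TRUE),
                    row.names = NULL)
  if (!is.null(signatures)) {
    k <- ncol(signatures)
    if (is.null(sig_weights)) sig_weights <- rep(1 / k, k)
    resp <- function(x, kept) {
      R <- t(signatures[x$context_idx[kept], , drop = FALSE]) * sig_weights
      sweep(R, 2, colSums(R), "/")
    }
    Ro <- resp(observed, keep_o); Rc <- resp(controls, keep_c)
    if (attribution == "hard") {
      Ro <- apply(Ro, 2, function(p) as.numeric(seq_len(k) == which.max(p)))
      Rc <- apply(Rc, 2, function(p) as.numeric(seq_len(k) == which.max(p)))
    }
    for (s in seq_len(k)) {
      osum <- tapply(Ro[s, ], fo, sum); osum[is.na(osum)] <- 0
      csum <- tapply(Rc[s, ], factor(cl, levels = classes), sum)
      r <- (osum / sum(Ro[s, ])) / (csum / sum(Rc[s, ]))
      out[[paste0("ratio_", colnames(signatures)[s])]] <- as.numeric(r)
    }
  }
  out
}

#' Assign genes to expression quintiles
#'
#' Genes are ranked by expression (CPM or any monotone transform), ties
#' broken by gene identifier, and split into five equal-rank groups, so that
#' quintile boundaries fall at the 20/40/60/80th percentiles and every gene
#' receives exactly one quintile even under heavy ties.
#'
#' @param expr numeric per-gene expression values.
#' @param gene_ids gene identifiers (used for tie-breaking and names).
#' @return Named integer vector of quintiles 1 (lowest) to 5 (highest).
#' @export
expressionQuintiles <- function(expr, gene_ids) {
  if (length(expr) < 5L) stop("need at least 5 genes for quintiles")
  if (length(expr) != length(gene_ids)) stop("expr and gene_ids must match")
  ord <- order(expr, gene_ids)
  q <- integer(length(expr))
  q[ord] <- ceiling(5 * seq_along(ord) / length(ord))
  setNames(q, gene_ids)
}

#' Transcriptional strand bias by substitution class and expression quantile
#'
#' Counts genic mutations on the transcribed versus untranscribed strand per
#' substitution class, overall and (when a quintile map is given) per
#' expression quintile.
#'
#' @param annotated annotated \linkS4class{MutationCatalog} (genic records
#'   with \code{tx_strand} assigned are used).
#' @param quintile_map optional named vector gene_id -> quintile.
#' @return data.frame with \code{sub_class}, \code{quantile} (\code{"all"}
#'   or 1-5), \code{n_transcribed}, \code{n_untranscribed} and
#'   \code{fraction_transcribed} (NA when the cell is empty).
#' @export
strandBias <- function(annotated, quintile_map = NULL) {
  g <- annotated[annotated$region == "genic"]
  qlev <- if (is.null(quintile_map)) "all" else c("all", as.character(1:5))
  rows <- list()
  for (sc in .SUBS) for (qq in qlev) {
    sel <- g$sub_class == sc
    if (qq != "all") sel <- sel & as.character(quintile_map[g$gene_id]) == qq
    nt <- sum(sel & g$tx_strand == "transcribed")
    nu <- sum(sel & g$tx_strand == "untranscribed")
    rows[[length(rows) + 1L]] <- data.frame(
      sub_class = sc, quantile = qq, n_transcribed = nt, n_untranscribed = nu,
      fraction_transcribed = if (nt + nu > 0) nt / (nt + nu) else NA_real_)
  }
  do.call(rbind, rows)
}

#' Somatic SNV rate per bp across gene-length deciles
#'
#' Ranks the genes of one class by length into deciles (ties by identifier),
#' computes each decile's mutation rate (mutations falling in the decile's
#' genes divided by the decile's total bp) and fits an ordinary least squares
#' line of rate on decile index.
#'
#' @param annotated annotated \linkS4class{MutationCatalog}.
#' @param genes \code{GRanges} of the genes of one class.
#' @param n_deciles number of length bins.
#' @return List with \code{table} (decile, n_genes, total_bp, n_mutations,
#'   rate) and \code{fit} (a \code{regression_fit} of rate on decile).
#' @export
snvRateByLength <- function(annotated, genes, n_deciles = 10L) {
  d <- .decileByLength(width(genes), genes$gene_id, n_deciles)
  cnt <- table(factor(annotated$gene_id[annotated$region == "genic"],
                      levels = genes$gene_id))
  tab <- data.frame(decile = seq_len(n_deciles))
  tab$n_genes <- as.integer(table(factor(d, levels = seq_len(n_deciles))))
  tab$total_bp <- as.numeric(tapply(width(genes), factor(d, levels = seq_len(n_deciles)), sum))
  tab$n_mutations <- as.integer(tapply(as.integer(cnt), factor(d, levels = seq_len(n_deciles)), sum))
  tab$rate <- tab$n_mutations / tab$total_bp
  fit <- burdenAgeRegression(tab$rate, tab$decile)
  list(table = tab, fit = fit)
}

#' Per-substitution-class spectrum comparison between two gene classes
#'
#' For each of the six substitution classes (and the pooled C>N aggregate),
#' tests whether class-A mutations are enriched for that substitution
#' relative to class-B mutations with a two-sided exact binomial test: the
#' count in A out of (A + B) for that substitution is tested against the
#' null proportion n_A / (n_A + n_B) of total mutation counts.
#'
#' @param classA,classB annotated \linkS4class{MutationCatalog}s (need the
#'   \code{sub_class} column), e.g. mutations in housekeeping versus
#'   neuron-specific genes.
#' @return data.frame with \code{sub_class} (six classes plus \code{"C>N"}),
#'   counts, the enrichment direction, the exact p (NA when untestable).
#' @export
classSpectrumTest <- function(classA, classB) {
  if (length(classA) == 0L || length(classB) == 0L)
    stop("both mutation classes must be nonempty")
  nA <- length(classA); nB <- length(classB)
  p0 <- nA / (nA + nB)
  groups <- c(as.list(.SUBS), list(c("C>A", "C>G", "C>T")))
  labels <- c(.SUBS, "C>N")
  rows <- lapply(seq_along(groups), function(i) {
    a <- sum(classA$sub_class %in% groups[[i]])
    b <- sum(classB$sub_class %in% groups[[i]])
    if (a + b == 0L)
      return(data.frame(sub_class = labels[i], n_A = 0L, n_B = 0L,
                        prop_A = NA_real_, null_prop = p0,
                        enriched_in_A = NA, p_value = NA_real_))
    bt <- binom.test(a, a + b, p = p0, alternative = "two.sided")
    data.frame(sub_class = labels[i], n_A = a, n_B = b,
               prop_A = a / (a + b), null_prop = p0,
               enriched_in_A = a / (a + b) > p0, p_value = bt$p.value)
  })
  do.call(rbind, rows)
}

#' Stopgain potential of each substitution class
#'
#' Enumerates all 64 codons and the 9 single-base substitutions of each,
#' counting per canonical substitution class the (codon, position, alternate)
#' events that turn a non-stop codon into a stop codon (TAA, TAG, TGA). Also
#' reports how many of the stop codons' nine bases are A or T (A/U on the
#' mRNA): 7 of 9, which is why C>T and C>A changes have the highest stopgain
#' potential.
#'
#' @return List with \code{per_class} (named count over the 6 substitution
#'   classes) and \code{stop_au_bases} (integer, out of 9).
#' @export
stopgainProfile <- function() {
  stops <- c("TAA", "TAG", "TGA")
  codons <- as.vector(outer(as.vector(outer(.BASES, .BASES, paste0)), .BASES, paste0))
  counts <- setNames(numeric(6L), .SUBS)
  for (cod in setdiff(codons, stops)) {
    for (pos in 1:3) {
      ref <- substr(cod, pos, pos)
      for (alt in setdiff(.BASES, ref)) {
        mut <- cod
        substr(mut, pos, pos) <- alt
        if (mut %in% stops) {
          cc <- canonicalContext(ref, alt, "A", "A")  # flanks irrelevant to class
          counts[cc$sub_class] <- counts[cc$sub_class] + 1
        }
      }
    }
  }
  au <- sum(strsplit(paste(stops, collapse = ""), NULL)[[1]] %in% c("A", "T"))
  list(per_class = counts, stop_au_bases = au)
}
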