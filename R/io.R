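#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#' @importFrom rtracklayer import export
#' @importFrom utils read.delim write.table
NULL

#' Read somatic SNVs from a VCF file
#'
#' Consumes biallelic single-nucleotide records from a per-cell VCF and tags
#' them with the cell and donor identity (per-cell VCFs carry no donor field,
#' so identity comes from the caller or a manifest, see
#' \code{\link{readMutationManifest}}). Indels, multiallelic records and
#' structural records are skipped; the number skipped is reported via a
#' message and stored in \code{metadata(x)$n_skipped}.
#'
#' @param path path to a VCF 4.x file.
#' @param cell_id,donor_id identity assigned to every record in the file.
#' @return A \linkS4class{MutationCatalog}.
#' @export
readMutationVCF <- function(path, cell_id, donor_id) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop("failed to parse VCF '", path, "': ", conditionMessage(e)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  n_in <- length(rr)
  snv <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
  rr <- rr[snv]
  n_skip <- n_in - length(rr)
  if (n_skip > 0)
    message("readMutationVCF: skipped ", n_skip, " non-SNV/multiallelic record(s) in ", basename(path))
  cat <- MutationCatalog(as.character(seqnames(rr)), start(rr),
                         as.character(rr$REF),
                         as.character(unlist(rr$ALT)),
                         cell_id = cell_id, donor_id = donor_id)
  metadata(cat)$n_skipped <- n_skip
  cat
}

#' Write a MutationCatalog as a minimal VCF 4.2 file
#'
#' @param x a \linkS4class{MutationCatalog}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMutationVCF <- function(x, path) {
  stopifnot(is(x, "MutationCatalog"))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=scSomaAging"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (length(x)) {
    o <- order(as.character(seqnames(x)), start(x))
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
            as.character(seqnames(x))[o], start(x)[o], x$ref[o], x$alt[o])
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read per-cell VCFs listed in a manifest
#'
#' The manifest is a TSV with columns \code{cell_id}, \code{donor_id},
#' \code{path} (paths relative to the manifest's directory or absolute).
#'
#' @param manifest_path path to the manifest TSV.
#' @return A single merged \linkS4class{MutationCatalog}.
#' @export
readMutationManifest <- function(manifest_path) {
  m <- read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "donor_id", "path")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  cats <- lapply(seq_len(nrow(m)), function(i) {
    p <- m$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    readMutationVCF(p, m$cell_id[i], m$donor_id[i])
  })
  out <- do.call(c, lapply(cats, function(x) as(x, "GRanges")))
  new("MutationCatalog", out)
}

#' Read gene annotations from GFF3 or BED
#'
#' Returns a \code{GRanges} of gene models with metadata columns
#' \code{gene_id} and \code{gene_length} (interval width). GFF3 input keeps
#' only \code{type == "gene"} records when a \code{type} column is present;
#' BED is interpreted as 0-based half-open and converted to the 1-based
#' closed GRanges convention on import. Overlapping genes are retained as-is;
#' overlap resolution is deferred to \code{\link{annotateMutations}}.
#'
#' @param path annotation file path.
#' @param dialect \code{"gff3"} or \code{"bed"}.
#' @return A \code{GRanges} of genes.
#' @export
readGeneAnnotation <- function(path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "gff3") "GFF3" else "BED"),
    error = function(e) stop("failed to parse ", dialect, " '", path, "': ",
                             conditionMessage(e)))
  if (dialect == "gff3" && "type" %in% colnames(mcols(gr)))
    gr <- gr[as.character(gr$type) == "gene"]
  if (any(width(gr) < 1L))
    stop("invalid interval with start > end in ", path)
  id <- if ("gene_id" %in% colnames(mcols(gr))) gr$gene_id
        else if ("ID" %in% colnames(mcols(gr))) gr$ID
        else if ("Name" %in% colnames(mcols(gr))) gr$Name
        else if ("name" %in% colnames(mcols(gr))) gr$name
        else paste0("gene_", seq_along(gr))
  mcols(gr) <- DataFrame(gene_id = as.character(id), gene_length = width(gr))
  gr
}

#' Packaged donor metadata
#'
#' The 13-donor table shipped with the package: one row per prefrontal-cortex
#' donor with age group (infant under 1 year, adults 15-57, elderly 82-104),
#' age in years, sex, the number of snRNA-seq nuclei passing QC and the
#' number of single neurons whole-genome sequenced. The nuclei counts sum to
#' 290,814 across donors (a mean of 22,370 per donor).
#'
#' @return A data.frame with columns \code{donor_id}, \code{group},
#'   \code{age_years}, \code{sex}, \code{n_nuclei}, \code{n_scwgs_cells}.
#' @examples
#' d <- donorTable()
#' sum(d$n_nuclei)   # 290814
#' @export
donorTable <- function() {
  p <- system.file("extdata", "donor_metadata.tsv", package = "scSomaAging",
                   mustWork = TRUE)
  d <- read.delim(p, stringsAsFactors = FALSE)
  d$group <- factor(d$group, levels = c("infant", "adult", "elderly"))
  d
}

#' Read a gene x cell count matrix with cell metadata
#'
#' Supports MatrixMarket triplet input (\code{matrix.mtx} plus
#' \code{genes.tsv} and \code{barcodes.tsv} in one directory) or a dense TSV
#' with gene ids in the first column. Cell metadata is a TSV with columns
#' \code{cell_id}, \code{cell_type}, \code{donor_id}, \code{age_group}.
#'
#' @param counts_path directory (MTX triplet) or TSV file.
#' @param cell_meta_path path to the cell-metadata TSV.
#' @return A \code{SingleCellExperiment} with a \code{counts} assay and the
#'   metadata in \code{colData}.
#' @export
readCountMatrix <- function(counts_path, cell_meta_path) {
  if (dir.exists(counts_path)) {
    m <- Matrix::readMM(file.path(counts_path, "matrix.mtx"))
    genes <- readLines(file.path(counts_path, "genes.tsv"))
    cells <- readLines(file.path(counts_path, "barcodes.tsv"))
    dimnames(m) <- list(genes, cells)
    counts <- as.matrix(m)
  } else {
    tab <- read.delim(counts_path, check.names = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- tab[[1]]
  }
  storage.mode(counts) <- "integer"
  meta <- read.delim(cell_meta_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "cell_type", "donor_id", "age_group")
  if (!all(need %in% names(meta)))
    stop("cell metadata must have columns: ", paste(need, collapse = ", "))
  if (!setequal(colnames(counts), meta$cell_id))
    stop("cell ids in counts and metadata disagree")
  meta <- meta[match(colnames(counts), meta$cell_id), ]
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = DataFrame(cell_type = meta$cell_type, donor_id = meta$donor_id,
                        age_group = meta$age_group, row.names = meta$cell_id))
}

#' Write a 96-bin spectrum (or signature) as TSV
#'
#' Two columns: the context label and the count (or probability). The same
#' layout is accepted back by \code{\link{readSignatureTSV}}, so externally
#' produced signature vectors (e.g. COSMIC v3 downloads) can be supplied.
#'
#' @param spectrum numeric vector of length 96, or a 96-row matrix (one
#'   column per sample/signature).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSpectrumTSV <- function(spectrum, path) {
  if (is.matrix(spectrum)) {
    stopifnot(nrow(spectrum) == 96L)
    df <- data.frame(context = contextLabels(), spectrum, check.names = FALSE)
  } else {
    stopifnot(length(spectrum) == 96L)
    df <- data.frame(context = contextLabels(), count = as.numeric(spectrum))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectrumTSV
#' @return \code{readSignatureTSV} returns a named numeric vector (single
#'   value column) or matrix (several columns) in the package's fixed context
#'   order, re-ordered by label if necessary.
#' @export
readSignatureTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) != 96L) stop("expected 96 rows in ", path)
  ord <- match(contextLabels(), df[[1]])
  if (anyNA(ord)) stop("context labels in ", path, " do not match the 96 canonical labels")
  vals <- as.matrix(df[ord, -1, drop = FALSE])
  rownames(vals) <- contextLabels()
  if (ncol(vals) == 1L) stats::setNames(as.numeric(vals), contextLabels()) else vals
}

#' Packaged reference signature vectors
#'
#' Two synthetic 96-context probability vectors shipped with the package and
#' used as the generator's ground-truth signatures: a flat-ish, T>C-weighted
#' "clock-like" vector (\code{"SBS5like"}) and a C>T-dominant vector
#' (\code{"SBS30like"}). They reproduce the qualitative shape of the COSMIC
#' v3 signatures they are named after but are constructed, not downloaded;
#' users comparing against the real COSMIC vectors can load them with
#' \code{\link{readSignatureTSV}}.
#'
#' @param name \code{"SBS5like"} or \code{"SBS30like"}.
#' @return Named numeric vector of length 96 summing to 1.
#' @export
referenceSignature <- function(name = c("SBS5like", "SBS30like")) {
  name <- match.arg(name)
  f <- if (name == "SBS5like") "signature_sbs5like_synthetic.tsv"
       else "signature_sbs30like_synthetic.tsv"
  p <- system.file("extdata", f, package = "scSomaAging", mustWork = TRUE)
  v <- readSignatureTSV(p)
  v / sum(v)
}
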