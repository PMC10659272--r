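#' @importFrom Biostrings DNAString
NULL

# trinucleotide (as character, plus strand) centered at each catalog position
.triAt <- function(genome, x) {
  chr <- as.character(seqnames(x))
  pos <- start(x)
  out <- character(length(x))
  for (ch in unique(chr)) {
    if (!ch %in% names(genome)) stop("chromosome '", ch, "' absent from reference")
    s <- genome[[ch]]
    i <- which(chr == ch)
    p <- pos[i]
    if (any(p < 2L | p > length(s) - 1L))
      stop("mutation position with flank outside reference on ", ch,
           " (record ", i[which(p < 2L | p > length(s) - 1L)[1]], ")")
    out[i] <- as.character(Biostrings::Views(s, start = p - 1L, end = p + 1L))
  }
  out
}

#' Build a 96-context mutation spectrum from a catalog
#'
#' Looks up each mutation's trinucleotide context in the reference,
#' collapses it to the pyrimidine-centered convention and counts mutations
#' per context bin. Mutations whose flanks contain a non-ACGT base (N) are
#' dropped, not imputed; the number dropped is reported.
#'
#' @param x a \linkS4class{MutationCatalog}.
#' @param genome a named \code{DNAStringSet} (or path to a FASTA file).
#' @param by optional metadata column name (e.g. \code{"cell_id"}); when
#'   given, a 96 x n matrix with one spectrum per group is returned in
#'   \code{$spectrum}.
#' @return A list with \code{spectrum} (named 96-vector, or matrix when
#'   \code{by} is given), \code{annotated} (the catalog with \code{context},
#'   \code{context_idx}, \code{sub_class}, \code{complemented} columns) and
#'   \code{n_dropped}.
#' @export
buildSpectrum <- function(x, genome, by = NULL) {
  stopifnot(is(x, "MutationCatalog"))
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  if (is.null(names(genome))) stop("reference sequences must be named")
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (length(x) == 0L) {
    spec <- if (is.null(by)) stats::setNames(numeric(96L), contextLabels())
            else matrix(0, 96L, 0L, dimnames = list(contextLabels(), NULL))
    return(list(spectrum = spec, annotated = x, n_dropped = 0L))
  }
  tri <- .triAt(genome, x)
  left <- substr(tri, 1L, 1L); ctr <- substr(tri, 2L, 2L); right <- substr(tri, 3L, 3L)
  bad <- !(left %in% .BASES & ctr %in% .BASES & right %in% .BASES)
  mism <- !bad & ctr != x$ref
  if (any(mism))
    stop("reference allele mismatch at record ", which(mism)[1],
         ": catalog says ", x$ref[which(mism)[1]], ", reference has ",
         ctr[which(mism)[1]])
  if (any(bad))
    message("buildSpectrum: dropped ", sum(bad), " mutation(s) with non-ACGT flank")
  keep <- which(!bad)
  ann <- x[keep]
  cc <- canonicalContext(ann$ref, ann$alt, left[keep], right[keep])
  mcols(ann)$context <- cc$label
  mcols(ann)$context_idx <- cc$index
  mcols(ann)$sub_class <- cc$sub_class
  mcols(ann)$complemented <- cc$complemented
  if (is.null(by)) {
    spec <- stats::setNames(as.numeric(tabulate(cc$index, nbins = 96L)), contextLabels())
  } else {
    grp <- factor(mcols(ann)[[by]])
    spec <- vapply(levels(grp),
                   function(g) tabulate(cc$index[grp == g], nbins = 96L),
                   numeric(96L))
    rownames(spec) <- contextLabels()
  }
  list(spectrum = spec, annotated = ann, n_dropped = sum(bad))
}

#' Cosine similarity between two nonnegative spectra
#'
#' @param u,v nonnegative numeric vectors of equal length, not all zero.
#' @return Cosine of the angle between \code{u} and \code{v}, in [0, 1] for
#'   nonnegative inputs; scale-invariant and symmetric.
#' @examples
#' cosineSim(c(1, 1, 0), c(1, 0, 0))  # 1/sqrt(2)
#' @export
cosineSim <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (any(u < 0) || any(v < 0)) stop("spectra must be nonnegative")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Frequency difference between two spectra
#'
#' Normalizes both spectra to frequencies and subtracts (\code{a - b}),
#' per 96-context bin and aggregated over the six substitution classes.
#'
#' @param a,b numeric 96-vectors with positive totals.
#' @return List with \code{per_bin} (named 96-vector) and \code{per_class}
#'   (named 6-vector).
#' @export
spectrumDifference <- function(a, b) {
  stopifnot(length(a) == 96L, length(b) == 96L)
  if (sum(a) <= 0 || sum(b) <= 0) stop("spectra must have positive totals")
  fa <- a / sum(a); fb <- b / sum(b)
  per_bin <- stats::setNames(fa - fb, contextLabels())
  cls <- contextClassIndex()
  per_class <- vapply(.SUBS, function(s) sum(per_bin[cls == s]), numeric(1))
  list(per_bin = per_bin, per_class = per_class)
}
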