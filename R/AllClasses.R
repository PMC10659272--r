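#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand findOverlaps
#' @importFrom IRanges IRanges
NULL

#' Catalog of somatic single-nucleotide variants
#'
#' A \code{MutationCatalog} is a \linkS4class{GRanges} of width-1 positions,
#' one per somatic SNV, carrying the alleles and the cell/donor provenance as
#' metadata columns \code{ref}, \code{alt}, \code{cell_id} and \code{donor_id}.
#' Coordinates follow the Bioconductor convention (1-based, closed);
#' conversions from other conventions happen only when files are read or
#' written.
#'
#' Annotation steps (\code{\link{annotateMutations}}, \code{\link{buildSpectrum}})
#' add further columns (\code{context}, \code{context_idx}, \code{complemented},
#' \code{gene_id}, \code{region}, \code{tx_strand}, \code{sub_class}) without
#' changing the class.
#'
#' @slot ranges inherited from \code{GRanges}; each range has width 1.
#' @seealso \code{\link{readMutationVCF}}, \code{\link{simulateMutations}}
#' @export
setClass("MutationCatalog", contains = "GRanges")

.validMutationCatalog <- function(object) {
  msg <- NULL
  need <- c("ref", "alt", "cell_id", "donor_id")
  miss <- setdiff(need, colnames(mcols(object)))
  if (length(miss))
    msg <- c(msg, paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (length(object) && is.null(msg)) {
    if (any(width(object) != 1L))
      msg <- c(msg, "all ranges must have width 1 (single-nucleotide variants only)")
    bad <- !(object$ref %in% c("A", "C", "G", "T")) | !(object$alt %in% c("A", "C", "G", "T"))
    if (any(bad))
      msg <- c(msg, "ref and alt must be single bases in {A,C,G,T}")
    if (any(object$ref == object$alt))
      msg <- c(msg, "ref must differ from alt")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("MutationCatalog", .validMutationCatalog)

#' Construct a MutationCatalog
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-base reference and alternate alleles.
#' @param cell_id,donor_id provenance identifiers (recycled if length 1).
#' @return A \linkS4class{MutationCatalog}.
#' @examples
#' MutationCatalog("chr1", 100L, "C", "T", cell_id = "c1", donor_id = "d1")
#' @export
MutationCatalog <- function(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            cell_id = character(), donor_id = character()) {
  n <- length(pos)
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
  mcols(gr) <- DataFrame(ref = rep_len(as.character(ref), n),
                         alt = rep_len(as.character(alt), n),
                         cell_id = rep_len(as.character(cell_id), n),
                         donor_id = rep_len(as.character(donor_id), n))
  new("MutationCatalog", gr)
}

#' @describeIn MutationCatalog reference alleles
#' @param x a \code{MutationCatalog}
#' @export
refAllele <- function(x) x$ref

#' @describeIn MutationCatalog alternate alleles
#' @export
altAllele <- function(x) x$alt

#' @describeIn MutationCatalog cell identifiers
#' @export
cellId <- function(x) x$cell_id

#' @describeIn MutationCatalog donor identifiers
#' @export
donorId <- function(x) x$donor_id

setMethod("show", "MutationCatalog", function(object) {
  cat("MutationCatalog with", length(object), "sSNV(s) from",
      length(unique(object$cell_id)), "cell(s) /",
      length(unique(object$donor_id)), "donor(s)\n")
  callNextMethod()
})

#' De novo mutational signatures with per-cell exposures
#'
#' Result container for \code{\link{nmfDecompose}}. Signatures are
#' column-stochastic distributions over the 96 trinucleotide contexts;
#' exposures are in mutation-count units, one column per cell.
#'
#' @slot signatures 96 x k nonnegative matrix, columns sum to 1.
#' @slot exposures k x n nonnegative matrix of per-cell signature loads.
#' @slot k integer rank.
#' @slot reconError generalized Kullback-Leibler divergence of the best fit.
#' @slot restartStability mean matched cosine of signatures across restarts.
#' @export
setClass("SignatureSet",
         representation(signatures = "matrix", exposures = "matrix",
                        k = "integer", reconError = "numeric",
                        restartStability = "numeric"))

.validSignatureSet <- function(object) {
  msg <- NULL
  if (nrow(object@signatures) != 96L)
    msg <- c(msg, "signatures must have 96 rows")
  if (ncol(object@signatures) != object@k)
    msg <- c(msg, "signatures must have k columns")
  if (nrow(object@exposures) != object@k)
    msg <- c(msg, "exposures must have k rows")
  if (any(object@signatures < 0) || any(object@exposures < 0))
    msg <- c(msg, "signatures and exposures must be nonnegative")
  cs <- colSums(object@signatures)
  if (any(abs(cs - 1) > 1e-6))
    msg <- c(msg, "signature columns must sum to 1")
  if (is.null(msg)) TRUE else msg
}
setValidity("SignatureSet", .validSignatureSet)

#' @describeIn SignatureSet the 96 x k signature matrix
#' @param object a \code{SignatureSet}
#' @export
setGeneric("signatures", function(object) standardGeneric("signatures"))

#' @rdname SignatureSet
#' @export
setMethod("signatures", "SignatureSet", function(object) object@signatures)

#' @describeIn SignatureSet the k x n exposure matrix (mutation counts)
#' @export
setGeneric("exposures", function(object) standardGeneric("exposures"))

#' @rdname SignatureSet
#' @export
setMethod("exposures", "SignatureSet", function(object) object@exposures)

#' @describeIn SignatureSet reconstruction divergence of the retained fit
#' @export
setGeneric("reconError", function(object) standardGeneric("reconError"))

#' @rdname SignatureSet
#' @export
setMethod("reconError", "SignatureSet", function(object) object@reconError)

#' @describeIn SignatureSet cross-restart stability in [0, 1]
#' @export
setGeneric("restartStability", function(object) standardGeneric("restartStability"))

#' @rdname SignatureSet
#' @export
setMethod("restartStability", "SignatureSet", function(object) object@restartStability)

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet: k =", object@k, "signatures over 96 contexts,",
      ncol(object@exposures), "cells\n")
  cat("  reconstruction divergence:", format(object@reconError, digits = 5), "\n")
  cat("  restart stability:", format(object@restartStability, digits = 4), "\n")
  tcm <- colSums(object@signatures[contextClassIndex() == "T>C", , drop = FALSE])
  ctm <- colSums(object@signatures[contextClassIndex() == "C>T", , drop = FALSE])
  for (i in seq_len(object@k))
    cat(sprintf("  %s: T>C mass %.2f, C>T mass %.2f\n",
                colnames(object@signatures)[i], tcm[i], ctm[i]))
})
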