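# 96 pyrimidine-centered trinucleotide substitution contexts, fixed layout:
# substitution (C>A, C>G, C>T, T>A, T>C, T>G) varies slowest, then the 5'
# flank, then the 3' flank, each over A, C, G, T. All serialization uses the
# context labels, never bare indices.

.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' The 96 trinucleotide substitution context labels
#'
#' Labels of the 96 pyrimidine-centered contexts in the package's fixed
#' lexicographic order: substitution class (C>A, C>G, C>T, T>A, T>C, T>G),
#' then 5' flank, then 3' flank, each flank over A, C, G, T. For example the
#' first label is \code{"A[C>A]A"} and the last is \code{"T[T>G]T"}.
#'
#' @return Character vector of length 96.
#' @export
contextLabels <- function() {
  out <- character(96L)
  i <- 0L
  for (s in .SUBS) for (l in .BASES) for (r in .BASES) {
    i <- i + 1L
    out[i] <- paste0(l, "[", s, "]", r)
  }
  out
}

#' @rdname contextLabels
#' @return \code{contextClassIndex} returns the substitution class
#'   (one of the 6) of each of the 96 context bins.
#' @export
contextClassIndex <- function() rep(.SUBS, each = 16L)

#' Collapse a substitution to its pyrimidine-centered context
#'
#' Maps a single-base substitution and its immediate flanks to one of the 96
#' canonical contexts. When the mutated base is a purine, the substitution
#' and both flanks are reverse-complemented so that the central base is C or
#' T (the standard convention for single-base-substitution spectra).
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param ref,alt reference and alternate base of the substitution.
#' @param left,right 5' and 3' flanking bases as read on the same strand as
#'   \code{ref}.
#' @return A data.frame with columns \code{index} (1-96, in the
#'   \code{\link{contextLabels}} order), \code{label}, \code{sub_class} and
#'   \code{complemented} (TRUE when the purine-centered input was flipped).
#' @examples
#' canonicalContext("C", "T", "T", "C")  # T[C>T]C, not complemented
#' canonicalContext("G", "A", "G", "A")  # also T[C>T]C, complemented
#' @export
canonicalContext <- function(ref, alt, left, right) {
  n <- max(length(ref), length(alt), length(left), length(right))
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  left <- rep_len(toupper(left), n); right <- rep_len(toupper(right), n)
  ok <- ref %in% .BASES & alt %in% .BASES & left %in% .BASES & right %in% .BASES
  if (!all(ok))
    stop("context unassignable: non-ACGT base at position(s) ",
         paste(utils::head(which(!ok), 5L), collapse = ", "),
         if (sum(!ok) > 5L) " ..." else "")
  if (any(ref == alt)) stop("ref must differ from alt")
  flip <- ref %in% c("A", "G")
  cref <- ifelse(flip, .COMP[ref], ref)
  calt <- ifelse(flip, .COMP[alt], alt)
  cleft <- ifelse(flip, .COMP[right], left)
  cright <- ifelse(flip, .COMP[left], right)
  si <- match(paste0(cref, ">", calt), .SUBS)
  li <- match(cleft, .BASES)
  ri <- match(cright, .BASES)
  idx <- (si - 1L) * 16L + (li - 1L) * 4L + ri
  data.frame(index = idx,
             label = paste0(cleft, "[", cref, ">", calt, "]", cright),
             sub_class = .SUBS[si],
             complemented = flip,
             stringsAsFactors = FALSE)
}

.revcomp <- function(x) {
  chartr("ACGT", "TGCA", sapply(strsplit(x, NULL), function(ch) paste(rev(ch), collapse = "")))
}

# 32 canonical pyrimidine-centered trinucleotides (the placement strata used
# for matched controls and the generator): index = (center==T)*16 + 5'*4 + 3'
.triLabels <- function() {
  out <- character(32L)
  i <- 0L
  for (ctr in c("C", "T")) for (l in .BASES) for (r in .BASES) {
    i <- i + 1L
    out[i] <- paste0(l, ctr, r)
  }
  out
}

# map a 96-context index to its canonical trinucleotide stratum (1-32)
.contextToTri <- function(idx) {
  si <- (idx - 1L) %/% 16L + 1L       # substitution class 1-6
  rest <- (idx - 1L) %% 16L           # 5' and 3' flank
  ctr <- ifelse(si <= 3L, 0L, 1L)     # C-centered vs T-centered
  ctr * 16L + rest + 1L
}
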