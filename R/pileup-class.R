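#' CohortPileup: per-site, per-sample read observations
#'
#' Container for the raw input of all callers: at each reference position,
#' the read bases and PHRED base qualities observed in every sample of the
#' cohort. Bases are stored as character strings over `ACGT` (one character
#' per read) and qualities as the matching PHRED+33 ASCII strings, the same
#' encoding used by the mpileup text format; a zero-depth cell is an empty
#' string in both matrices.
#'
#' @slot rowRanges `GRanges` of width-1 positions with an mcols column
#'   `REF` giving the reference base.
#' @slot samples Character vector of sample identifiers (column order).
#' @slot bases,quals Character matrices, sites x samples.
#'
#' @aliases CohortPileup-class
#' @export CohortPileup
#' @exportClass CohortPileup
CohortPileup <- setClass("CohortPileup",
  slots = c(rowRanges = "GRanges", samples = "character",
            bases = "matrix", quals = "matrix"))

setValidity("CohortPileup", function(object) {
  S <- length(object@rowRanges)
  N <- length(object@samples)
  msg <- character()
  if (!identical(dim(object@bases), c(S, N)) ||
      !identical(dim(object@quals), c(S, N)))
    msg <- c(msg, "bases/quals dimensions must be sites x samples")
  if (is.null(mcols(object@rowRanges)$REF) ||
      !all(mcols(object@rowRanges)$REF %in% .ALLELES))
    msg <- c(msg, "rowRanges must carry a REF column of A/C/G/T")
  if (length(msg) == 0 &&
      any(nchar(object@bases) != nchar(object@quals)))
    msg <- c(msg, "per-cell base and quality strings must have equal length")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortPileup
#'
#' @param chrom,pos,ref Site coordinates (1-based) and reference bases.
#' @param samples Sample identifiers.
#' @param bases,quals Character matrices (sites x samples) of read bases
#'   (`ACGT`) and PHRED+33 qualities.
#' @return A `CohortPileup`.
#' @export
cohortPileup <- function(chrom, pos, ref, samples, bases, quals) {
  stopifnot(all(pos >= 1))
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(gr)$REF <- as.character(ref)
  bases <- as.matrix(bases)
  quals <- as.matrix(quals)
  dimnames(bases) <- dimnames(quals) <- list(NULL, samples)
  new("CohortPileup", rowRanges = gr, samples = as.character(samples),
      bases = bases, quals = quals)
}

#' @describeIn CohortPileup-class read-base string matrix
#' @export
setMethod("pileupBases", "CohortPileup", function(x) x@bases)

#' @describeIn CohortPileup-class PHRED+33 quality string matrix
#' @export
setMethod("pileupQuals", "CohortPileup", function(x) x@quals)

#' @describeIn CohortPileup-class sample identifiers
#' @export
setMethod("sampleIds", "CohortPileup", function(x) x@samples)

#' @describeIn CohortPileup-class site positions as `GRanges`
#' @export
setMethod("rowRanges", "CohortPileup", function(x, ...) x@rowRanges)

#' @describeIn CohortPileup-class reference bases
#' @export
setMethod("refAllele", "CohortPileup", function(x) mcols(x@rowRanges)$REF)

#' @describeIn CohortPileup-class per-cell read depth matrix
#' @export
setMethod("dpMatrix", "CohortPileup", function(x) {
  d <- nchar(x@bases)
  dimnames(d) <- dimnames(x@bases)
  d
})

setMethod("show", "CohortPileup", function(object) {
  d <- nchar(object@bases)
  cat("CohortPileup:", length(object@rowRanges), "sites x",
      length(object@samples), "samples\n")
  cat("  mean depth:", round(mean(d), 2),
      " depth range:", paste(range(d), collapse = "-"), "\n")
})

#' Subset a pileup
#'
#' `[` subsets sites (i) and samples (j, by index or name).
#' @param x A `CohortPileup`.
#' @param i,j Site and sample indexes.
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "CohortPileup", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@rowRanges)
  if (missing(j)) j <- seq_along(x@samples)
  if (is.character(j)) j <- match(j, x@samples)
  new("CohortPileup", rowRanges = x@rowRanges[i],
      samples = x@samples[j],
      bases = x@bases[i, j, drop = FALSE],
      quals = x@quals[i, j, drop = FALSE])
})
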