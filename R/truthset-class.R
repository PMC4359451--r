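#' TruthSet: simulated ground truth
#'
#' Ground truth accompanying a synthetic cohort: true genotypes for every
#' sample (replicates included) at every simulated site, true allele
#' frequencies, polymorphism and artifact flags, and the replicate pairing
#' map.
#'
#' @slot rowRanges Width-1 `GRanges` with columns `REF`, `ALT`, `af`
#'   (realised sample alternate-allele frequency), `is_variant` and
#'   `is_artifact`.
#' @slot genotypes Integer genotype-code matrix, sites x samples.
#' @slot pairs `data.frame` with columns `sample` and `replicate`.
#'
#' @aliases TruthSet-class
#' @export TruthSet
#' @exportClass TruthSet
TruthSet <- setClass("TruthSet",
  slots = c(rowRanges = "GRanges", genotypes = "matrix", pairs = "data.frame"))

setValidity("TruthSet", function(object) {
  msg <- character()
  if (nrow(object@genotypes) != length(object@rowRanges))
    msg <- c(msg, "genotype rows must match rowRanges")
  m <- mcols(object@rowRanges)
  need <- c("REF", "ALT", "af", "is_variant", "is_artifact")
  if (!all(need %in% names(m)))
    msg <- c(msg, paste("rowRanges must carry", paste(need, collapse = ", ")))
  else if (any(m$is_variant & m$is_artifact))
    msg <- c(msg, "artifact labels must be disjoint from true variants")
  if (length(msg)) msg else TRUE
})

#' @describeIn TruthSet-class true genotype-code matrix
#' @param x A `TruthSet`.
#' @export
setMethod("truthGenotypes", "TruthSet", function(x) x@genotypes)

#' @describeIn TruthSet-class replicate pairing map
#' @export
setMethod("replicatePairs", "TruthSet", function(x) x@pairs)

#' @describeIn TruthSet-class site positions
#' @export
setMethod("rowRanges", "TruthSet", function(x, ...) x@rowRanges)

#' @describeIn TruthSet-class sample identifiers
#' @export
setMethod("sampleIds", "TruthSet", function(x) colnames(x@genotypes))

setMethod("show", "TruthSet", function(object) {
  m <- mcols(object@rowRanges)
  cat("TruthSet:", length(object@rowRanges), "sites x",
      ncol(object@genotypes), "samples;",
      sum(m$is_variant), "true variants,", sum(m$is_artifact),
      "artifact sites,", nrow(object@pairs), "replicate pairs\n")
})

#' View a TruthSet as a CallSet
#'
#' Wraps the true genotypes in a [CallSet] (caller `"TRUTH"`) so the
#' evaluation statistics (e.g. [hetMismatch()]) can compare call sets
#' directly against the simulated truth.
#'
#' @param truth A `TruthSet`.
#' @return A [CallSet] over the truth sites.
#' @export
truthCallSet <- function(truth) {
  gr <- rowRanges(truth)
  callSet(granges(gr), ref = mcols(gr)$REF,
          alt = as.list(mcols(gr)$ALT),
          assays = list(GT = truthGenotypes(truth)),
          samples = colnames(truthGenotypes(truth)), caller = "TRUTH",
          af = mcols(gr)$af)
}
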