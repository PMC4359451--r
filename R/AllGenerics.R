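#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#'   rowRanges colData assay<-
#' @importFrom Rcpp evalCpp
#' @useDynLib capturecall, .registration = TRUE
NULL

#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))

#' @export
setGeneric("altAlleles", function(x) standardGeneric("altAlleles"))

#' @export
setGeneric("gtMatrix", function(x, ...) standardGeneric("gtMatrix"))

#' @export
setGeneric("gqMatrix", function(x) standardGeneric("gqMatrix"))

#' @export
setGeneric("dpMatrix", function(x) standardGeneric("dpMatrix"))

#' @export
setGeneric("siteQual", function(x) standardGeneric("siteQual"))

#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))

#' @export
setGeneric("imputeRsq", function(x) standardGeneric("imputeRsq"))

#' @export
setGeneric("callerKind", function(x) standardGeneric("callerKind"))

#' @export
setGeneric("pileupBases", function(x) standardGeneric("pileupBases"))

#' @export
setGeneric("pileupQuals", function(x) standardGeneric("pileupQuals"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("truthGenotypes", function(x) standardGeneric("truthGenotypes"))

#' @export
setGeneric("replicatePairs", function(x) standardGeneric("replicatePairs"))
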