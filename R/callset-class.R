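#' CallSet: a sites-by-samples genotype call matrix
#'
#' Extends `RangedSummarizedExperiment`. Rows are variant sites (width-1
#' `GRanges` with `REF`, an `ALT` `CharacterList`, site quality `QUAL`,
#' allele frequency `AF` and, for LD-refined sets, imputation quality `R2`);
#' columns are samples. Assays always include `GT` (integer genotype codes,
#' see [gtIsHet()]), and depending on the caller `GQ`, `DP`, log-likelihood
#' triplets `LRR`/`LRA`/`LAA`, dosages `DS`, posterior triplets
#' `PRR`/`PRA`/`PAA` and posterior ratios `PR`. `metadata()$caller` is one
#' of `"IBC"`, `"PBC"`, `"LDC"` or `"CHIP"`.
#'
#' @aliases CallSet-class
#' @export CallSet
#' @exportClass CallSet
CallSet <- setClass("CallSet", contains = "RangedSummarizedExperiment")

setValidity("CallSet", function(object) {
  msg <- character()
  if (!"GT" %in% assayNames(object))
    msg <- c(msg, "CallSet requires a GT assay")
  rr <- rowRanges(object)
  if (length(rr)) {
    if (is.null(mcols(rr)$REF)) msg <- c(msg, "rowRanges needs a REF column")
    if (is.null(mcols(rr)$ALT)) msg <- c(msg, "rowRanges needs an ALT column")
  }
  if (is.null(metadata(object)$caller))
    msg <- c(msg, "metadata()$caller must identify the caller kind")
  if (length(msg)) msg else TRUE
})

#' Construct a CallSet
#'
#' @param gr Width-1 `GRanges` of variant sites.
#' @param ref,alt Reference base and list of alternate bases per site
#'   (`alt` a list or `CharacterList`).
#' @param assays Named list of sites-x-samples matrices; must contain `GT`.
#' @param samples Sample identifiers.
#' @param caller Caller kind string.
#' @param qual,af,rsq Optional per-site quality, alternate-allele frequency
#'   and imputation R-squared.
#' @param ... Extra entries stored in `metadata()`.
#' @return A `CallSet`.
#' @export
callSet <- function(gr, ref, alt, assays, samples, caller,
                    qual = NA_real_, af = NA_real_, rsq = NULL, ...) {
  mcols(gr)$REF <- as.character(ref)
  mcols(gr)$ALT <- IRanges::CharacterList(alt)
  mcols(gr)$QUAL <- rep_len(qual, length(gr))
  mcols(gr)$AF <- rep_len(af, length(gr))
  if (!is.null(rsq)) mcols(gr)$R2 <- rep_len(rsq, length(gr))
  assays <- lapply(assays, function(a) {
    dimnames(a) <- list(NULL, samples)
    a
  })
  se <- SummarizedExperiment(assays = assays, rowRanges = gr,
                             colData = DataFrame(row.names = samples))
  metadata(se)$caller <- caller
  extra <- list(...)
  for (nm in names(extra)) metadata(se)[[nm]] <- extra[[nm]]
  new("CallSet", se)
}

#' @describeIn CallSet-class genotype code matrix (`NA` = missing)
#' @param x,object A `CallSet`.
#' @export
setMethod("gtMatrix", "CallSet", function(x, ...) assay(x, "GT"))

#' @describeIn CallSet-class genotype quality (PHRED) matrix
#' @export
setMethod("gqMatrix", "CallSet", function(x) assay(x, "GQ"))

#' @describeIn CallSet-class genotype depth matrix
#' @export
setMethod("dpMatrix", "CallSet", function(x) assay(x, "DP"))

#' @describeIn CallSet-class reference bases
#' @export
setMethod("refAllele", "CallSet", function(x) mcols(rowRanges(x))$REF)

#' @describeIn CallSet-class alternate alleles (`CharacterList`)
#' @export
setMethod("altAlleles", "CallSet", function(x) mcols(rowRanges(x))$ALT)

#' @describeIn CallSet-class PHRED-scaled site quality
#' @export
setMethod("siteQual", "CallSet", function(x) mcols(rowRanges(x))$QUAL)

#' @describeIn CallSet-class alternate-allele frequency estimate
#' @export
setMethod("alleleFreq", "CallSet", function(x) mcols(rowRanges(x))$AF)

#' @describeIn CallSet-class per-site imputation R-squared (LDC)
#' @export
setMethod("imputeRsq", "CallSet", function(x) mcols(rowRanges(x))$R2)

#' @describeIn CallSet-class caller kind
#' @export
setMethod("callerKind", "CallSet", function(x) metadata(x)$caller)

#' @describeIn CallSet-class sample identifiers
#' @export
setMethod("sampleIds", "CallSet", function(x) colnames(x))

setMethod("show", "CallSet", function(object) {
  gt <- assay(object, "GT")
  cat("CallSet (", metadata(object)$caller, "): ", nrow(object), " sites x ",
      ncol(object), " samples\n", sep = "")
  if (nrow(object)) {
    nalt <- lengths(altAlleles(object))
    cat("  multi-allelic sites:", sum(nalt > 1),
        "  missing genotypes:", sprintf("%.2f%%", 100 * mean(is.na(gt))), "\n")
  }
})

## site keys used when matching call sets by locus
.siteKey <- function(x) {
  gr <- rowRanges(x)
  paste0(as.character(seqnames(gr)), ":", start(gr))
}
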