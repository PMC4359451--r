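## Shared genotype bookkeeping: the four alleles, the ten unordered diploid
## genotypes in fixed alphabetical order, and the integer encoding used for
## genotype matrices throughout the package.

.ALLELES <- c("A", "C", "G", "T")

## alphabetical unordered pairs: AA AC AG AT CC CG CT GG GT TT
.GENO_PAIRS <- cbind(
  a1 = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L),
  a2 = c(1L, 2L, 3L, 4L, 2L, 3L, 4L, 3L, 4L, 4L)
)
.GENO_NAMES <- paste0(.ALLELES[.GENO_PAIRS[, 1]], .ALLELES[.GENO_PAIRS[, 2]])

#' The ten diploid genotypes
#'
#' Names of the ten unordered diploid single-nucleotide genotypes in the
#' fixed (alphabetical) order used everywhere in the package, e.g. for
#' likelihood vectors and deterministic tie-breaking.
#'
#' @return Character vector of length 10 (`"AA"`, `"AC"`, ..., `"TT"`).
#' @export
genotypeNames <- function() .GENO_NAMES

#' @rdname genotypeNames
#' @return `alleleNames()`: the four nucleotides `"A" "C" "G" "T"`.
#' @export
alleleNames <- function() .ALLELES

## index (1..10) of the unordered genotype {a1, a2}; a1/a2 are 1..4
.genoIndex <- function(a1, a2) {
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  match((lo - 1L) * 10L + hi, (.GENO_PAIRS[, 1] - 1L) * 10L + .GENO_PAIRS[, 2])
}

## --- GT cell encoding -------------------------------------------------------
## A genotype cell in a CallSet is an integer 10*i1 + i2 where i1 <= i2 are
## VCF-style allele indexes into the site's allele list (0 = REF). NA encodes
## a missing genotype. Biallelic hom-ref/het/hom-alt are therefore 0, 1, 11.

.gtCode <- function(i1, i2) {
  lo <- pmin(i1, i2)
  hi <- pmax(i1, i2)
  as.integer(10L * lo + hi)
}

.gtFirst <- function(code) code %/% 10L
.gtSecond <- function(code) code %% 10L

#' Genotype-cell helpers
#'
#' Genotype cells are integers `10*i1 + i2` with `i1 <= i2` VCF-style allele
#' indexes (0 = REF); `NA` marks a missing genotype. `gtIsHet()` flags
#' heterozygous cells, `gtDosage()` counts copies of a given alternate
#' allele index, and `gtText()` renders `"i1/i2"` strings (`"./."` when
#' missing).
#'
#' @param code Integer vector (or matrix) of genotype codes.
#' @param alt_index Alternate-allele index counted by `gtDosage()` (default 1).
#' @return Logical, integer or character objects shaped like `code`.
#' @export
gtIsHet <- function(code) {
  out <- .gtFirst(code) != .gtSecond(code)
  out
}

#' @rdname gtIsHet
#' @export
gtDosage <- function(code, alt_index = 1L) {
  (. <- (.gtFirst(code) == alt_index) + (.gtSecond(code) == alt_index))
}

#' @rdname gtIsHet
#' @export
gtText <- function(code) {
  out <- ifelse(is.na(code), "./.", paste0(.gtFirst(code), "/", .gtSecond(code)))
  if (is.matrix(code)) dim(out) <- dim(code)
  out
}

## transition pairs among {A,C,G,T}: A<->G, C<->T
.isTransition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}
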