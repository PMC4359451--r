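#' PHRED score to error probability
#'
#' Converts an integer PHRED base quality to an error probability,
#' `10^(-q/10)`, capped at `error_floor_cap` so that a Q0 base never has
#' probability 1 of being wrong (which would make likelihoods degenerate).
#'
#' @param q Non-negative integer PHRED score(s).
#' @param params A [modelParams()] list (supplies the cap, default 0.75).
#' @return Error probabilities in `(0, error_floor_cap]`.
#' @examples
#' phredToError(20)  # 0.01
#' phredToError(0)   # capped at 0.75
#' @export
phredToError <- function(q, params = modelParams()) {
  if (any(q < 0)) stop("PHRED scores must be non-negative")
  pmin(10^(-q / 10), params$error_floor_cap)
}

#' Per-base emission probability
#'
#' Probability of observing read base `b` from a diploid genotype, with the
#' standard consensus-caller convention: a sequencing error turns the true
#' base into each of the other three bases with probability `e/3`, and the
#' read is drawn from either genotype allele with probability 1/2.
#'
#' @param b Observed base (`"A"`, `"C"`, `"G"`, `"T"`).
#' @param genotype Genotype name, e.g. `"AC"` (order of the two alleles is
#'   irrelevant).
#' @param e Per-base error probability in `(0, 1)`.
#' @return Emission probability in `(0, 1)`.
#' @examples
#' baseEmission("A", "AA", 0.01)  # 0.99
#' baseEmission("A", "AC", 0.01)  # (0.99 + 0.01/3)/2
#' @export
baseEmission <- function(b, genotype, e) {
  stopifnot(e > 0, e < 1)
  al <- strsplit(genotype, "")[[1]]
  if (length(al) != 2 || !all(al %in% .ALLELES) || !b %in% .ALLELES)
    stop("invalid base or genotype")
  p <- function(a) if (b == a) 1 - e else e / 3
  0.5 * p(al[1]) + 0.5 * p(al[2])
}

#' Genotype likelihoods for one sample at one site
#'
#' Log-likelihood of each of the ten diploid genotypes given the observed
#' reads, assuming independent per-base errors: the sum over reads of the
#' log per-base emission. The vector is renormalised so its maximum is 0;
#' with zero reads all ten values are 0 (flat).
#'
#' @param bases Character vector of read bases.
#' @param quals Integer PHRED qualities (same length).
#' @param params A [modelParams()] list.
#' @return List with `loglik` (named length-10 numeric, max 0) and `depth`.
#' @export
genotypeLikelihoods <- function(bases, quals, params = modelParams()) {
  if (length(bases) != length(quals))
    stop("bases and quals must have the same length")
  codes <- match(bases, .ALLELES) - 1L
  if (anyNA(codes)) stop("invalid read base")
  errs <- phredToError(quals, params)
  ll <- cpp_gl_column(codes, errs)
  names(ll) <- .GENO_NAMES
  list(loglik = ll, depth = length(bases))
}

#' Posterior genotype probabilities
#'
#' Combines a genotype log-likelihood vector with a log prior by Bayes'
#' rule, computed in log space with max-subtraction.
#'
#' @param loglik Length-10 log-likelihood vector.
#' @param logprior Length-10 log prior; `exp(logprior)` must sum to 1.
#' @return Length-10 posterior probabilities summing to 1.
#' @export
posteriorFromLoglik <- function(loglik, logprior) {
  if (abs(sum(exp(logprior)) - 1) > 1e-6)
    stop("prior must be normalised over the 10 genotypes")
  w <- loglik + logprior
  w <- w - max(w)
  p <- exp(w)
  p / sum(p)
}

#' Genotype likelihoods for a whole pileup
#'
#' Computes the 10-genotype log-likelihood vector for every site/sample
#' cell of a [CohortPileup] (compiled kernel; the per-cell result is
#' identical to [genotypeLikelihoods()]).
#'
#' @param pileup A `CohortPileup`.
#' @param params A [modelParams()] list.
#' @return List with `loglik` (array `10 x sites x samples`, per-cell max
#'   0, genotype order [genotypeNames()]) and `depth` (sites x samples).
#' @export
genotypeLikelihoodArray <- function(pileup, params = modelParams()) {
  out <- cpp_gl_pileup(pileupBases(pileup), pileupQuals(pileup),
                       params$error_floor_cap)
  dimnames(out$loglik) <- list(.GENO_NAMES, NULL, sampleIds(pileup))
  dimnames(out$depth) <- list(NULL, sampleIds(pileup))
  out
}

## Collapse a 10-genotype log-likelihood array to biallelic triplets
## (RR, RA, AA) for per-site ref/alt allele indexes (1..4).
## gl: 10 x S x N array; ref, alt: length-S allele indexes.
## Returns list of S x N matrices LRR, LRA, LAA (log scale, cellwise
## renormalised so the triplet max is 0).
.biallelicTriplets <- function(gl, ref, alt) {
  S <- dim(gl)[2]
  N <- dim(gl)[3]
  iRR <- .genoIndex(ref, ref)
  iRA <- .genoIndex(ref, alt)
  iAA <- .genoIndex(alt, alt)
  idx <- function(g) {
    ## index into 10 x S x N array at genotype g (per site), all samples
    outer((g - 1L) + (seq_len(S) - 1L) * 10L, (seq_len(N) - 1L) * (10L * S), "+") + 1L
  }
  LRR <- matrix(gl[idx(iRR)], S, N)
  LRA <- matrix(gl[idx(iRA)], S, N)
  LAA <- matrix(gl[idx(iAA)], S, N)
  mx <- pmax(LRR, LRA, LAA)
  list(LRR = LRR - mx, LRA = LRA - mx, LAA = LAA - mx)
}
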