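#' Individual-based genotype prior
#'
#' Prior over the ten diploid genotypes given the reference base, built
#' from the per-allele reference-mismatch rate `theta`. Alternate alleles
#' are exchangeable, i.e. transitions and transversions get equal prior
#' mass, so the prior cannot bias Ts/Tv-based quality assessment.
#'
#' Two parameterisations are available. `"independent"` treats the two
#' allele draws as independent (hom-ref `(1-theta)^2`, each specific
#' ref-alt het `2(1-theta)theta/3`, each hom-alt `(theta/3)^2`). Because a
#' hom-alt then has prior `~theta^2/9`, hom-alt calls need very deep data;
#' the default `"dependent"` mode uses the consensus-caller allocation of
#' `theta/3` per specific ref-alt het and `theta/6` per specific hom-alt
#' (total het mass `theta`, hom-alt mass `theta/2`). Alt-alt heterozygotes
#' keep the independent-model mass `2(theta/3)^2` in both modes so
#' multi-allelic genotypes remain callable.
#'
#' @param ref Reference base.
#' @param params A [modelParams()] list.
#' @param mode `"dependent"` (default) or `"independent"`.
#' @return List with `mode` and `probs` (named length-10 vector summing
#'   to 1).
#' @export
ibcPrior <- function(ref, params = modelParams(),
                     mode = c("dependent", "independent")) {
  mode <- match.arg(mode)
  th <- params$theta
  r <- match(ref, .ALLELES)
  if (is.na(r)) stop("invalid reference allele")
  p <- numeric(10)
  isR1 <- .GENO_PAIRS[, 1] == r
  isR2 <- .GENO_PAIRS[, 2] == r
  homref <- isR1 & isR2
  het_ref <- xor(isR1, isR2)
  hom_alt <- !isR1 & !isR2 & .GENO_PAIRS[, 1] == .GENO_PAIRS[, 2]
  het_alt <- !isR1 & !isR2 & .GENO_PAIRS[, 1] != .GENO_PAIRS[, 2]
  if (mode == "independent") {
    p[homref] <- (1 - th)^2
    p[het_ref] <- 2 * (1 - th) * th / 3
    p[hom_alt] <- (th / 3)^2
    p[het_alt] <- 2 * (th / 3)^2
  } else {
    p[het_ref] <- th / 3
    p[hom_alt] <- th / 6
    p[het_alt] <- 2 * (th / 3)^2
    p[homref] <- 1 - sum(p)
    if (p[homref] <= 0) stop("theta too large for a proper prior")
  }
  names(p) <- .GENO_NAMES
  list(mode = mode, probs = p / sum(p))
}

#' Call one genotype with the individual-based model
#'
#' Posterior over the ten genotypes from the likelihoods and the
#' individual-based prior; the argmax genotype is called when its posterior
#' reaches `posterior_threshold` (99% by default), otherwise the genotype
#' is missing. Ties break by the fixed alphabetical genotype order.
#'
#' @param gl Output of [genotypeLikelihoods()].
#' @param prior Output of [ibcPrior()].
#' @param params A [modelParams()] list.
#' @return List with `genotype` (name or `NA`), `gq` (PHRED-scaled
#'   `-10*log10(1 - posterior)`, capped at 100), `depth` and
#'   `posterior_max`.
#' @export
callGenotypeIbc <- function(gl, prior, params = modelParams()) {
  post <- posteriorFromLoglik(gl$loglik, log(prior$probs))
  i <- which.max(post)  # first max = alphabetical tie-break
  pm <- post[[i]]
  called <- pm >= params$posterior_threshold
  list(genotype = if (called) .GENO_NAMES[i] else NA_character_,
       genotype_index = if (called) i else NA_integer_,
       gq = min(100, -10 * log10(max(1 - pm, 1e-10))),
       depth = gl$depth, posterior_max = pm)
}

#' Individual-based single-marker calling over a cohort
#'
#' Runs the individual-based caller on every cell of a pileup (reference
#' homozygotes included) and assembles the union call set of all variant
#' sites: a site is emitted when at least one non-missing called genotype
#' carries a non-reference allele, and its allele list is the reference
#' plus the union of called alternate alleles (multi-allelic sites
#' supported).
#'
#' @param pileup A [CohortPileup].
#' @param params A [modelParams()] list.
#' @param prior_mode Prior parameterisation, see [ibcPrior()].
#' @return A [CallSet] (caller `"IBC"`) with assays `GT`, `GQ`, `DP`.
#'   Site `QUAL` is the summed genotype quality of the variant carriers,
#'   capped at 255.
#' @export
callIBC <- function(pileup, params = modelParams(),
                    prior_mode = c("dependent", "independent")) {
  prior_mode <- match.arg(prior_mode)
  ga <- genotypeLikelihoodArray(pileup, params)
  ref <- refAllele(pileup)
  S <- dim(ga$loglik)[2]
  N <- dim(ga$loglik)[3]

  geno <- matrix(NA_integer_, S, N)   # called 10-genotype index or NA
  gq <- matrix(NA_real_, S, N)
  pm <- matrix(NA_real_, S, N)
  for (rb in unique(ref)) {
    rows <- which(ref == rb)
    lp <- log(ibcPrior(rb, params, prior_mode)$probs)
    w <- matrix(ga$loglik[, rows, , drop = FALSE], nrow = 10) + lp
    mx <- do.call(pmax, lapply(seq_len(10), function(g) w[g, ]))
    pw <- exp(w - rep(mx, each = 10))
    tot <- colSums(pw)
    best <- max.col(t(pw), ties.method = "first")
    pbest <- pw[cbind(best, seq_along(best))] / tot
    gidx <- ifelse(pbest >= params$posterior_threshold, best, NA_integer_)
    geno[rows, ] <- matrix(gidx, length(rows), N)
    pm[rows, ] <- matrix(pbest, length(rows), N)
    gq[rows, ] <- matrix(pmin(100, -10 * log10(pmax(1 - pbest, 1e-10))),
                         length(rows), N)
  }
  gq[is.na(geno)] <- NA_real_

  buildUnionCallset(geno, gq, ga$depth, rowRanges(pileup),
                    sampleIds(pileup), params = params)
}

#' Assemble the union call set from per-sample calls
#'
#' Takes the matrix of called genotypes (10-genotype indexes, `NA` for
#' missing) across all samples and sites and keeps the sites where at least
#' one called genotype carries a non-reference allele. The site allele list
#' is the reference plus the union of called alternate alleles, ordered by
#' called-allele count (ties alphabetical); allele counts and frequencies
#' are computed from non-missing genotypes only.
#'
#' @param geno Sites x samples matrix of 10-genotype indexes (`NA` missing).
#' @param gq,depth Matching genotype-quality and depth matrices.
#' @param gr Width-1 `GRanges` with a `REF` mcols column.
#' @param samples Sample identifiers.
#' @param params A [modelParams()] list (stored in the result).
#' @return A [CallSet] of the variant sites.
#' @export
buildUnionCallset <- function(geno, gq, depth, gr, samples,
                              params = modelParams()) {
  ref <- mcols(gr)$REF
  if (is.null(ref)) stop("gr must carry a REF column")
  if (anyNA(ref) || !all(ref %in% .ALLELES))
    stop("inconsistent or invalid reference alleles")
  S <- nrow(geno)
  a1 <- matrix(.GENO_PAIRS[geno, 1], S)
  a2 <- matrix(.GENO_PAIRS[geno, 2], S)
  rr <- match(ref, .ALLELES)

  ## per-site allele counts over called genotypes
  cnt <- vapply(seq_len(4), function(a)
    rowSums(a1 == a, na.rm = TRUE) + rowSums(a2 == a, na.rm = TRUE),
    numeric(S))
  if (S == 1) cnt <- matrix(cnt, 1)
  nonref <- cnt
  nonref[cbind(seq_len(S), rr)] <- 0
  keep <- which(rowSums(nonref) > 0)

  alt_list <- vector("list", length(keep))
  gt <- matrix(NA_integer_, length(keep), ncol(geno))
  af <- numeric(length(keep))
  qual <- numeric(length(keep))
  for (i in seq_along(keep)) {
    s <- keep[i]
    alts <- setdiff(order(-nonref[s, ], seq_len(4))[seq_len(sum(nonref[s, ] > 0))],
                    rr[s])
    alt_list[[i]] <- .ALLELES[alts]
    amap <- integer(4)                      # allele base -> VCF index
    amap[rr[s]] <- 0L
    amap[alts] <- seq_along(alts)
    i1 <- amap[a1[s, ]]
    i2 <- amap[a2[s, ]]
    gt[i, ] <- ifelse(is.na(a1[s, ]), NA_integer_, .gtCode(i1, i2))
    ncalled <- sum(!is.na(a1[s, ]))
    af[i] <- sum(nonref[s, alts]) / max(1, 2 * ncalled)
    carriers <- which(!is.na(gt[i, ]) & gt[i, ] != 0L)
    qual[i] <- min(255, sum(gq[s, carriers]))
  }
  callSet(granges(gr[keep]), ref = ref[keep], alt = alt_list,
          assays = list(GT = gt,
                        GQ = gq[keep, , drop = FALSE],
                        DP = depth[keep, , drop = FALSE]),
          samples = samples, caller = "IBC", qual = qual, af = af,
          params = params)
}
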