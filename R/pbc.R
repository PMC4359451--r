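#' Neutral-model polymorphism prior
#'
#' Prior probability that a site is polymorphic in a sample of
#' `n_chromosomes` chromosomes under the stationary neutral model:
#' Watterson's expected segregation probability
#' `theta * sum(1/i, i = 1..n-1)`, capped (default 0.5) so it stays a
#' proper prior at very large sample sizes.
#'
#' @param n_chromosomes Number of sampled chromosomes (>= 2).
#' @param params A [modelParams()] list (supplies `theta` and the cap).
#' @return Prior probability of polymorphism.
#' @examples
#' polymorphismPrior(2)      # theta
#' polymorphismPrior(15684)  # ~0.0102 for the 7,842-diploid cohort
#' @export
polymorphismPrior <- function(n_chromosomes, params = modelParams()) {
  if (n_chromosomes < 2) stop("need at least 2 chromosomes")
  min(params$prior_cap, params$theta * sum(1 / seq_len(n_chromosomes - 1)))
}

#' Choose the alternate allele at a site
#'
#' The population-based caller is biallelic: among non-reference bases
#' observed across the cohort, the alternate allele is the base with the
#' highest quality-weighted read count (weight `1 - e` per read), ties
#' broken by the fixed A<C<G<T order.
#'
#' @param bases Character vector of all reads at the site (cohort-wide).
#' @param quals Matching PHRED qualities.
#' @param ref Reference base.
#' @param params A [modelParams()] list.
#' @return The alternate base, or `NA` if no non-reference read is seen
#'   (the site is then skipped, not an error).
#' @export
chooseAlt <- function(bases, quals, ref, params = modelParams()) {
  w <- 1 - phredToError(quals, params)
  keep <- bases != ref
  if (!any(keep)) return(NA_character_)
  tot <- vapply(.ALLELES, function(a) sum(w[keep][bases[keep] == a]), 0)
  tot[ref] <- -Inf
  .ALLELES[which.max(tot)]
}

#' Population allele frequency by EM under Hardy-Weinberg
#'
#' Maximum-likelihood estimate of the alternate-allele frequency `f` from
#' per-sample biallelic likelihood triplets, assuming Hardy-Weinberg
#' genotype proportions `{(1-f)^2, 2f(1-f), f^2}`. EM iterates
#' `f <- mean(E[alt alleles | f]) / 2`; it starts from the
#' quality-weighted non-reference read fraction (floored at `1/(2n)`) and
#' stops when `|delta f| < 1e-6` or after 100 iterations. Without a
#' supplied start the climb is repeated from a small set of starting
#' values (moment estimate, floor, 0.5, upper floor) and the best
#' likelihood wins, since the mixture likelihood of small conflicting
#' cohorts can be multimodal.
#'
#' @param triplets n x 3 matrix of per-sample likelihoods
#'   `(L_RR, L_RA, L_AA)` (linear scale, any per-sample normalisation).
#' @param f0 Starting value (e.g. a read-derived fraction); if `NULL`,
#'   multi-start as described above.
#' @param tol,max_iter Convergence tolerance and iteration cap.
#' @return The estimate `f_hat`.
#' @export
estimateFreqEM <- function(triplets, f0 = NULL, tol = 1e-6, max_iter = 100L) {
  triplets <- as.matrix(triplets)
  n <- nrow(triplets)
  if (n < 1) stop("empty cohort")
  if (any(triplets < 0) || any(rowSums(triplets) == 0))
    stop("likelihood triplets must be non-negative and not all zero")
  floor_f <- 1 / (2 * n)
  loglik <- function(f)
    sum(log(triplets[, 1] * (1 - f)^2 + triplets[, 2] * 2 * f * (1 - f) +
            triplets[, 3] * f^2))
  climb <- function(f) {
    for (it in seq_len(max_iter)) {
      w0 <- triplets[, 1] * (1 - f)^2
      w1 <- triplets[, 2] * 2 * f * (1 - f)
      w2 <- triplets[, 3] * f^2
      tot <- w0 + w1 + w2
      zero <- tot == 0
      if (any(zero)) { w1[zero] <- 1; tot[zero] <- 3 }  # flat fallback
      fn <- sum((w1 + 2 * w2) / tot) / (2 * n)
      fn <- min(max(fn, floor_f), 1 - 1e-9)
      if (abs(fn - f) < tol) return(fn)
      f <- fn
    }
    f
  }
  ## the mixture log-likelihood can be multimodal for small, conflicting
  ## cohorts; without an informative start, climb from several and keep the
  ## best. A moment start (flat-prior expected dosage) covers most cases.
  if (is.null(f0)) {
    moment <- mean((triplets[, 2] + 2 * triplets[, 3]) /
                   (2 * rowSums(triplets)))
    starts <- unique(pmin(pmax(c(moment, floor_f, 0.5, 1 - floor_f),
                               floor_f), 1 - 1e-9))
  } else {
    starts <- max(f0, floor_f)
  }
  cand <- vapply(starts, climb, 0)
  cand[which.max(vapply(cand, loglik, 0))]
}

#' Polymorphism posterior and site quality
#'
#' Posterior probability that the site is polymorphic:
#' `P = prior*L1 / (prior*L1 + (1-prior)*L0)` where `L1` is the cohort
#' likelihood under Hardy-Weinberg at `f_hat` and `L0` the likelihood of
#' everyone being reference-homozygous. Site quality is
#' `-10*log10(1 - P)`, capped at 255.
#'
#' @param triplets n x 3 likelihood triplets (linear scale).
#' @param f_hat Estimated alternate-allele frequency.
#' @param prior_poly Polymorphism prior, see [polymorphismPrior()].
#' @param params A [modelParams()] list (emission threshold).
#' @return List with `is_variant`, `site_qual` and `posterior`.
#' @export
variantPosterior <- function(triplets, f_hat, prior_poly,
                             params = modelParams()) {
  triplets <- as.matrix(triplets)
  l1 <- sum(log(triplets[, 1] * (1 - f_hat)^2 +
                triplets[, 2] * 2 * f_hat * (1 - f_hat) +
                triplets[, 3] * f_hat^2))
  l0 <- sum(log(triplets[, 1]))
  ## posterior odds in log space
  log_odds <- log(prior_poly) - log1p(-prior_poly) + l1 - l0
  p <- 1 / (1 + exp(-log_odds))
  qual <- min(255, -10 * log10(max(1 - p, 1e-26)))
  list(is_variant = qual > params$emit_threshold, site_qual = qual,
       posterior = p)
}

#' Genotype calls with the allele-frequency prior
#'
#' Per-sample posterior over `{RR, RA, AA}` combining the likelihood
#' triplet with the Hardy-Weinberg prior at `f_hat`; the argmax genotype is
#' called when its posterior reaches the 99% threshold, otherwise missing.
#'
#' @param triplets n x 3 likelihood triplets.
#' @param f_hat Estimated alternate-allele frequency.
#' @param params A [modelParams()] list.
#' @return List of vectors `genotype` (0 = hom-ref, 1 = het, 2 = hom-alt,
#'   `NA` = missing), `gq` and `posterior` (n x 3 matrix).
#' @export
callGenotypesPbc <- function(triplets, f_hat, params = modelParams()) {
  triplets <- as.matrix(triplets)
  prior <- c((1 - f_hat)^2, 2 * f_hat * (1 - f_hat), f_hat^2)
  w <- sweep(triplets, 2, prior, "*")
  w <- w / rowSums(w)
  best <- max.col(w, ties.method = "first") - 1L
  pbest <- w[cbind(seq_len(nrow(w)), best + 1L)]
  called <- pbest >= params$posterior_threshold
  list(genotype = ifelse(called, best, NA_integer_),
       gq = pmin(100, -10 * log10(pmax(1 - pbest, 1e-10))),
       posterior = w)
}

#' Population-based single-marker calling over a cohort
#'
#' Two-step caller: at every site with at least one non-reference read it
#' picks the alternate allele, estimates the population allele frequency by
#' EM under Hardy-Weinberg, computes the polymorphism posterior against the
#' neutral-model prior, and calls per-sample genotypes with the
#' allele-frequency prior. Only sites whose quality exceeds the emission
#' threshold are returned.
#'
#' @param pileup A [CohortPileup].
#' @param params A [modelParams()] list.
#' @param samples Optional subset of sample ids to call (e.g. one member of
#'   each replicate pair per run).
#' @param sites Optional integer vector of site rows to evaluate.
#' @return A [CallSet] (caller `"PBC"`) with assays `GT`, `GQ`, `DP` and
#'   the log-likelihood triplets `LRR`/`LRA`/`LAA` used by the LD refiner;
#'   site `QUAL` is the polymorphism quality and `AF` the EM frequency
#'   estimate.
#' @export
callPBC <- function(pileup, params = modelParams(), samples = NULL,
                    sites = NULL) {
  if (!is.null(samples)) pileup <- pileup[, match(samples, sampleIds(pileup))]
  if (!is.null(sites)) pileup <- pileup[sites, ]
  ga <- genotypeLikelihoodArray(pileup, params)
  ref <- refAllele(pileup)
  S <- length(ref)
  N <- length(sampleIds(pileup))
  prior_poly <- polymorphismPrior(2 * N, params)

  ## quality-weighted per-base read weights per site (cohort-wide)
  bmat <- pileupBases(pileup)
  qmat <- pileupQuals(pileup)
  alt <- rep(NA_character_, S)
  f0 <- rep(NA_real_, S)
  for (s in seq_len(S)) {
    bs <- strsplit(paste(bmat[s, ], collapse = ""), "")[[1]]
    if (length(bs) == 0) next
    qs <- utf8ToInt(paste(qmat[s, ], collapse = "")) - 33L
    a <- chooseAlt(bs, qs, ref[s], params)
    if (is.na(a)) next
    alt[s] <- a
    w <- 1 - phredToError(qs, params)
    f0[s] <- sum(w[bs == a]) / sum(w)
  }
  cand <- which(!is.na(alt))

  refi <- match(ref, .ALLELES)
  alti <- match(alt, .ALLELES)
  alti[is.na(alti)] <- refi[is.na(alti)] %% 4L + 1L  # placeholder, unused
  trip <- .biallelicTriplets(ga$loglik, refi, alti)
  eRR <- exp(trip$LRR); eRA <- exp(trip$LRA); eAA <- exp(trip$LAA)

  ## vectorised EM across candidate sites
  f <- pmax(f0[cand], 1 / (2 * N))
  R0 <- eRR[cand, , drop = FALSE]
  R1 <- eRA[cand, , drop = FALSE]
  R2 <- eAA[cand, , drop = FALSE]
  active <- rep(TRUE, length(cand))
  for (it in seq_len(100)) {
    if (!any(active)) break
    fa <- f[active]
    w0 <- R0[active, , drop = FALSE] * (1 - fa)^2
    w1 <- R1[active, , drop = FALSE] * (2 * fa * (1 - fa))
    w2 <- R2[active, , drop = FALSE] * fa^2
    tot <- w0 + w1 + w2
    fn <- rowSums((w1 + 2 * w2) / tot) / (2 * N)
    fn <- pmin(pmax(fn, 1 / (2 * N)), 1 - 1e-9)
    conv <- abs(fn - fa) < 1e-6
    f[active] <- fn
    active[active] <- !conv
  }

  ## polymorphism posterior and genotypes
  qual <- numeric(length(cand))
  pvar <- numeric(length(cand))
  l1 <- rowSums(log(R0 * (1 - f)^2 + R1 * (2 * f * (1 - f)) + R2 * f^2))
  l0 <- rowSums(log(R0))
  log_odds <- log(prior_poly) - log1p(-prior_poly) + l1 - l0
  pvar <- 1 / (1 + exp(-log_odds))
  qual <- pmin(255, -10 * log10(pmax(1 - pvar, 1e-26)))
  emit <- which(qual > params$emit_threshold)

  keep <- cand[emit]
  n_keep <- length(keep)
  gt <- matrix(NA_integer_, n_keep, N)
  gq <- matrix(NA_real_, n_keep, N)
  if (n_keep) {
    fk <- f[emit]
    p0 <- R0[emit, , drop = FALSE] * (1 - fk)^2
    p1 <- R1[emit, , drop = FALSE] * (2 * fk * (1 - fk))
    p2 <- R2[emit, , drop = FALSE] * fk^2
    tot <- p0 + p1 + p2
    p0 <- p0 / tot; p1 <- p1 / tot; p2 <- p2 / tot
    pbest <- pmax(p0, p1, p2)
    best <- (p1 == pbest) * 1L + (p2 == pbest & p1 != pbest) * 2L
    ## ties resolved toward the lower genotype by construction above
    best[p0 == pbest] <- 0L
    gt <- matrix(ifelse(pbest >= params$posterior_threshold,
                        ifelse(best == 2L, 11L, best), NA_integer_),
                 n_keep, N)
    gq <- matrix(pmin(100, -10 * log10(pmax(1 - pbest, 1e-10))), n_keep, N)
  }

  gr <- rowRanges(pileup)[keep]
  cs <- callSet(granges(gr), ref = ref[keep],
                alt = as.list(alt[keep]),
                assays = list(GT = gt, GQ = gq,
                              DP = ga$depth[keep, , drop = FALSE],
                              LRR = trip$LRR[keep, , drop = FALSE],
                              LRA = trip$LRA[keep, , drop = FALSE],
                              LAA = trip$LAA[keep, , drop = FALSE]),
                samples = sampleIds(pileup), caller = "PBC",
                qual = qual[emit], af = f[emit],
                params = params, prior_poly = prior_poly)
  cs
}
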