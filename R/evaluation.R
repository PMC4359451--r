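#' Transition/transversion ratio
#'
#' Ratio of transition (A<->G, C<->T) to transversion substitutions across
#' the sites of a call set; a multi-allelic site contributes one ref-alt
#' pair per alternate allele. A ratio above ~2 is expected genome-wide and
#' is a standard call-set quality indicator.
#'
#' @param x A [CallSet], or a `data.frame` with columns `ref` and `alt`.
#' @return List with `tstv` (`NA` and `defined = FALSE` when there are no
#'   transversions), `transitions`, `transversions`.
#' @export
tstv <- function(x) {
  if (is(x, "CallSet")) {
    ref <- rep(refAllele(x), lengths(altAlleles(x)))
    alt <- unlist(altAlleles(x), use.names = FALSE)
  } else {
    ref <- x$ref
    alt <- x$alt
  }
  ts <- sum(.isTransition(ref, alt))
  tv <- length(ref) - ts
  list(tstv = if (tv > 0) ts / tv else NA_real_,
       defined = tv > 0, transitions = ts, transversions = tv)
}

#' Heterozygote mismatch rate between two call sets
#'
#' The number of genotypes called heterozygous in one set but homozygous in
#' the other, divided by the total number of heterozygous genotypes in both
#' sets. Sites are matched by position, samples by name; a cell missing in
#' either set is excluded. The statistic is symmetric in its two arguments.
#'
#' @param csA,csB Two [CallSet]s (e.g. a caller vs chip genotypes, or two
#'   callers).
#' @param sites Optional restriction: site keys (`"chrom:pos"`) to use.
#' @param samples Optional restriction of the shared samples.
#' @return A `concordance_report` list: `n_het_A`, `n_het_B`,
#'   `n_mismatch`, `h_e`.
#' @export
hetMismatch <- function(csA, csB, sites = NULL, samples = NULL) {
  kA <- .siteKey(csA)
  kB <- .siteKey(csB)
  shared <- intersect(kA, kB)
  if (!is.null(sites)) shared <- intersect(shared, sites)
  ss <- intersect(colnames(csA), colnames(csB))
  if (!is.null(samples)) ss <- intersect(ss, samples)
  if (!length(shared) || !length(ss))
    stop("no shared sites/samples between the call sets")
  gA <- gtMatrix(csA)[match(shared, kA), ss, drop = FALSE]
  gB <- gtMatrix(csB)[match(shared, kB), ss, drop = FALSE]
  ok <- !is.na(gA) & !is.na(gB)
  hA <- gtIsHet(gA) & ok
  hB <- gtIsHet(gB) & ok
  n_mm <- sum((hA & !hB & ok) | (hB & !hA & ok))
  n_hA <- sum(hA)
  n_hB <- sum(hB)
  structure(list(n_het_A = n_hA, n_het_B = n_hB, n_mismatch = n_mm,
                 h_e = if (n_hA + n_hB > 0) n_mm / (n_hA + n_hB) else 0,
                 n_sites = length(shared), n_samples = length(ss)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("heterozygote mismatch: %d / (%d + %d) = %.4f%%\n",
              x$n_mismatch, x$n_het_A, x$n_het_B, 100 * x$h_e))
  invisible(x)
}

#' Replicate-pair concordance
#'
#' Heterozygote mismatch rate between the two members of each sequencing
#' replicate pair, restricted to variant sites where at least one member of
#' the pair is heterozygous (per pair). Members may live in the same call
#' set or in two call sets from separate runs.
#'
#' @param csA Call set containing the first members.
#' @param pairs `data.frame` with columns `sample` and `replicate`.
#' @param csB Call set containing the second members (default `csA`).
#' @return A `concordance_report`.
#' @export
replicateConcordance <- function(csA, pairs, csB = csA) {
  if (!all(pairs$sample %in% colnames(csA)) ||
      !all(pairs$replicate %in% colnames(csB)))
    stop("replicate pair members missing from the call sets")
  kA <- .siteKey(csA)
  kB <- .siteKey(csB)
  shared <- intersect(kA, kB)
  n_mm <- 0L; n_h <- 0L
  for (p in seq_len(nrow(pairs))) {
    gA <- gtMatrix(csA)[match(shared, kA), pairs$sample[p]]
    gB <- gtMatrix(csB)[match(shared, kB), pairs$replicate[p]]
    ok <- !is.na(gA) & !is.na(gB)
    hA <- gtIsHet(gA) & ok
    hB <- gtIsHet(gB) & ok
    use <- ok & (hA | hB)   # at least one member heterozygous
    n_mm <- n_mm + sum(use & (hA != hB))
    n_h <- n_h + sum(hA[use]) + sum(hB[use])
  }
  structure(list(n_het_A = NA_integer_, n_het_B = NA_integer_,
                 n_mismatch = n_mm,
                 h_e = if (n_h > 0) n_mm / n_h else 0,
                 n_sites = length(shared), n_samples = 2L * nrow(pairs)),
            class = "concordance_report")
}

#' Audit of additional heterozygotes called by a more complex caller
#'
#' Finds heterozygous genotypes that a more complex caller produced at
#' cells where a simpler caller had a missing genotype, and reports how
#' many there are and their heterozygote mismatch rate against a truth (or
#' chip) call set.
#'
#' @param simple,complex Two [CallSet]s over the same cohort.
#' @param truth Reference genotypes as a [CallSet] (chip or truth).
#' @param sites Optional site-key restriction (e.g. chip marker positions).
#' @return List with `n_extra_hets` and `h_e` of those genotypes versus
#'   the reference.
#' @export
additionalHetAudit <- function(simple, complex, truth, sites = NULL) {
  kS <- .siteKey(simple)
  kC <- .siteKey(complex)
  kT <- .siteKey(truth)
  shared <- Reduce(intersect, list(kS, kC, kT))
  if (!is.null(sites)) shared <- intersect(shared, sites)
  ss <- Reduce(intersect, list(colnames(simple), colnames(complex),
                               colnames(truth)))
  gS <- gtMatrix(simple)[match(shared, kS), ss, drop = FALSE]
  gC <- gtMatrix(complex)[match(shared, kC), ss, drop = FALSE]
  gT <- gtMatrix(truth)[match(shared, kT), ss, drop = FALSE]
  extra <- is.na(gS) & !is.na(gC) & gtIsHet(gC) & !is.na(gT)
  n_extra <- sum(extra)
  if (n_extra == 0)
    return(list(n_extra_hets = 0L, h_e = NA_real_, n_mismatch = 0L))
  tru_het <- gtIsHet(gT)[extra]
  n_mm <- sum(!tru_het)                 # het in complex, hom in truth
  list(n_extra_hets = n_extra,
       h_e = n_mm / (n_extra + sum(tru_het)),
       n_mismatch = n_mm)
}

#' Fraction of missing genotypes
#'
#' Missing genotype cells (no-calls plus filtered genotypes) over all
#' cells of the call set.
#'
#' @param callset A [CallSet].
#' @return Fraction in `[0, 1]`.
#' @export
missingness <- function(callset) {
  mean(is.na(gtMatrix(callset)))
}

#' Singleton and caller-specific site summary
#'
#' Characterises the sites specific to each of two call sets: singleton
#' status (minor allele observed exactly once among non-missing
#' genotypes), Ts/Tv per subset, the read depth of the singleton carrier,
#' and the truth-validation rate of caller-specific singletons when a
#' truth set is available.
#'
#' @param csA,csB Two [CallSet]s.
#' @param truth Optional [TruthSet].
#' @return List with per-set summaries `a_specific` and `b_specific`
#'   (counts, singleton counts, `tstv`, `carrier_depth`, `validated`
#'   fraction) and the singleton site keys of each set.
#' @export
singletonSummary <- function(csA, csB, truth = NULL) {
  one <- function(cs) {
    gt <- gtMatrix(cs)
    ac <- rowSums(gtDosage(gt), na.rm = TRUE)
    n2 <- 2 * rowSums(!is.na(gt))
    mac <- pmin(ac, n2 - ac)
    is_single <- mac == 1
    carrier <- rep(NA_integer_, nrow(gt))
    for (s in which(is_single)) {
      ## a minor allele count of 1 means exactly one heterozygous carrier
      j <- which(!is.na(gt[s, ]) & gtIsHet(gt[s, ]))
      carrier[s] <- if (length(j)) j[1] else NA_integer_
    }
    list(singleton = is_single, carrier = carrier)
  }
  kA <- .siteKey(csA)
  kB <- .siteKey(csB)
  sA <- one(csA)
  sB <- one(csB)
  one_side <- function(cs, k, other_k, s) {
    specific <- !(k %in% other_k)
    sing <- specific & s$singleton
    dp <- dpMatrix(cs)
    cd <- ifelse(sing, dp[cbind(seq_len(nrow(cs)), s$carrier)], NA_real_)
    val <- NA_real_
    if (!is.null(truth)) {
      tg <- rowRanges(truth)
      tk <- paste0(as.character(seqnames(tg)), ":", start(tg))
      tv <- tk[mcols(tg)$is_variant]
      val <- if (any(sing)) mean(k[sing] %in% tv) else NA_real_
    }
    list(n_specific = sum(specific), n_specific_singletons = sum(sing),
         tstv = if (any(sing)) tstv(data.frame(
           ref = refAllele(cs)[sing],
           alt = vapply(altAlleles(cs)[sing], `[`, "", 1)))$tstv else NA_real_,
         carrier_depth = cd[sing & !is.na(cd)],
         validated = val,
         singleton_keys = k[s$singleton],
         specific_singleton_keys = k[sing])
  }
  list(a_specific = one_side(csA, kA, kB, sA),
       b_specific = one_side(csB, kB, kA, sB))
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Two-sided p-value by direct hypergeometric enumeration, summing all
#' tables with point probability at most that of the observed table (with
#' a `1 + 1e-7` relative tolerance, the minimum-likelihood convention).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(30, 0, 38, 3), 2, byrow = TRUE))  # 0.2575
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0),
            all(tab == round(tab)))
  if (sum(tab) == 0) stop("all-zero table")
  m <- sum(tab[1, ])            # row-1 total
  n <- sum(tab[2, ])            # row-2 total
  k <- sum(tab[, 1])            # column-1 total
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  sum(d[d <= d[support == x] * (1 + 1e-7)])
}

#' Down-sampling singleton recovery experiment
#'
#' Evaluates the ability of the population-based caller to recover a
#' reference set of singletons (typically the individual-based caller's
#' singletons from the full cohort) in nested random sub-cohorts built by
#' sequentially adding individuals. For each subset size the function
#' reports the fraction of reference singletons whose carrier is in the
#' subset and which the population-based caller emits as variant with the
#' carrier called heterozygous (with and without the genotype-quality
#' filter), together with the mean site quality of the recovered
#' singletons; results are averaged over replicates.
#'
#' @param pileup The full-cohort [CohortPileup].
#' @param singleton_keys Site keys (`"chrom:pos"`) of the reference
#'   singletons.
#' @param carriers Sample id of the singleton carrier per site.
#' @param sizes Sub-cohort sizes (increasing; must not exceed the cohort).
#' @param reps Number of independent sampling replicates.
#' @param params A [modelParams()] list.
#' @return `data.frame` with one row per size: mean `recovered` (fraction,
#'   no genotype filter), `recovered_filtered` (carrier GQ >= 20) and
#'   `mean_qual`; plus `sizes` and `reps` attributes.
#' @export
downsamplingExperiment <- function(pileup, singleton_keys, carriers, sizes,
                                   reps = 1, params = modelParams()) {
  all_samples <- sampleIds(pileup)
  if (max(sizes) > length(all_samples)) stop("subset size exceeds cohort")
  pk <- paste0(as.character(seqnames(rowRanges(pileup))), ":",
               start(rowRanges(pileup)))
  rows <- match(singleton_keys, pk)
  if (anyNA(rows)) stop("singleton sites missing from the pileup")
  acc <- array(0, dim = c(length(sizes), 3))
  for (r in seq_len(reps)) {
    perm <- sample(all_samples)
    for (i in seq_along(sizes)) {
      sub <- perm[seq_len(sizes[i])]
      present <- carriers %in% sub
      if (!any(present)) next
      cs <- callPBC(pileup[rows[present], match(sub, all_samples)], params)
      k <- .siteKey(cs)
      keys_p <- singleton_keys[present]
      hit <- match(keys_p, k)
      rec <- rec_f <- logical(length(keys_p))
      qual <- rep(NA_real_, length(keys_p))
      found <- !is.na(hit)
      if (any(found)) {
        g <- gtMatrix(cs)[hit[found], , drop = FALSE]
        gq <- gqMatrix(cs)[hit[found], , drop = FALSE]
        cj <- match(carriers[present][found], colnames(cs))
        gc <- g[cbind(seq_len(nrow(g)), cj)]
        qc <- gq[cbind(seq_len(nrow(g)), cj)]
        rec[found] <- !is.na(gc) & gtIsHet(gc)
        rec_f[found] <- rec[found] & qc >= 20
        qual[found] <- siteQual(cs)[hit[found]]
      }
      acc[i, 1] <- acc[i, 1] + mean(rec)
      acc[i, 2] <- acc[i, 2] + mean(rec_f)
      acc[i, 3] <- acc[i, 3] + mean(qual[rec], na.rm = TRUE)
    }
  }
  out <- data.frame(size = sizes,
                    recovered = acc[, 1] / reps,
                    recovered_filtered = acc[, 2] / reps,
                    mean_qual = acc[, 3] / reps)
  attr(out, "reps") <- reps
  out
}

#' Overlap with a known-site list
#'
#' Fraction of the call set's sites present in a known-variant table
#' (dbSNP-like), matched by chromosome, position and alternate allele.
#'
#' @param callset A [CallSet].
#' @param known `data.frame` with columns `chrom`, `pos`, `alt`.
#' @return Fraction in `[0, 1]`.
#' @export
siteListOverlap <- function(callset, known) {
  if (nrow(callset) == 0) return(NA_real_)
  if (nrow(known) == 0) return(0)
  kk <- paste0(known$chrom, ":", known$pos, ":", known$alt)
  gr <- rowRanges(callset)
  keys <- paste0(rep(as.character(seqnames(gr)), lengths(altAlleles(callset))),
                 ":", rep(start(gr), lengths(altAlleles(callset))),
                 ":", unlist(altAlleles(callset), use.names = FALSE))
  site <- rep(seq_len(nrow(callset)), lengths(altAlleles(callset)))
  hit <- tapply(keys %in% kk, site, any)
  mean(hit)
}
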