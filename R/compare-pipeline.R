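#' Run the three calling strategies on one synthetic cohort
#'
#' Convenience pipeline for method comparison: calls the cohort with the
#' individual-based and population-based callers, refines the
#' population-based calls with the LD-aware refiner (with and, optionally,
#' without the flanking chip scaffold), applies each caller's genotype
#' filters, and collects the headline comparison statistics (missingness,
#' heterozygote mismatch against the masked on-target chip genotypes,
#' truth concordance, Ts/Tv).
#'
#' @param sim Output of [simulateCohort()].
#' @param hc An [hmmConfig()] for the refiner.
#' @param params A [modelParams()] list.
#' @param ldc_no_flank Also run the refiner without the scaffold.
#' @return List with the filtered call sets (`ibc`, `pbc`, `ldc`,
#'   optionally `ldc_no_flank`), the unfiltered ones (`*_raw`) and a
#'   `metrics` data.frame (one row per caller).
#' @export
compareCallers <- function(sim, hc = hmmConfig(), params = modelParams(),
                           ldc_no_flank = FALSE) {
  ibc0 <- callIBC(sim$pileup, params)
  pbc0 <- callPBC(sim$pileup, params)
  ldc0 <- refineLD(pbc0, sim$scaffold, sim$targets, hc, params)
  out <- list(ibc_raw = ibc0, pbc_raw = pbc0, ldc_raw = ldc0,
              ibc = applyGenotypeFilters(ibc0),
              pbc = applyGenotypeFilters(pbc0),
              ldc = applyGenotypeFilters(ldc0))
  if (ldc_no_flank) {
    out$ldc_no_flank_raw <- refineLD(pbc0, NULL, NULL, hc, params)
    out$ldc_no_flank <- applyGenotypeFilters(out$ldc_no_flank_raw)
  }
  callers <- intersect(c("ibc", "pbc", "ldc", "ldc_no_flank"), names(out))
  tcs <- truthCallSet(sim$truth)
  chip_keys <- .siteKey(sim$scaffold)
  out$metrics <- do.call(rbind, lapply(callers, function(nm) {
    cs <- out[[nm]]
    data.frame(caller = nm,
               n_sites = nrow(cs),
               missingness = missingness(cs),
               he_chip = hetMismatch(cs, sim$scaffold)$h_e,
               he_truth = hetMismatch(cs, tcs, sites = chip_keys)$h_e,
               tstv = tstv(cs)$tstv,
               concordance = .truthConc(cs, sim$truth))
  }))
  out
}

## genotype concordance with the truth over non-missing cells
.truthConc <- function(cs, truth) {
  tk <- paste0(as.character(seqnames(rowRanges(truth))), ":",
               start(rowRanges(truth)))
  k <- .siteKey(cs)
  m <- match(k, tk)
  ok <- !is.na(m)
  g <- gtMatrix(cs)[ok, , drop = FALSE]
  t2 <- truthGenotypes(truth)[m[ok], colnames(cs), drop = FALSE]
  mean(g == t2, na.rm = TRUE)
}

#' Count true singletons recovered at low carrier depth
#'
#' For the comparison of singleton discovery between callers: counts the
#' true singleton sites (one heterozygous carrier in the truth) whose
#' carrier has read depth below `max_depth` and whose carrier genotype the
#' call set reports heterozygous with genotype quality at or above
#' `min_gq` (the depth filter is deliberately not applied, matching how
#' low-coverage singleton discovery is audited).
#'
#' @param callset A (raw, unfiltered) [CallSet].
#' @param truth The [TruthSet].
#' @param pileup The [CohortPileup] (for carrier depth).
#' @param max_depth Carrier depth bound (exclusive; default 10).
#' @param min_gq Genotype-quality bound (default 20).
#' @return List with `n_called` and `n_eligible`.
#' @export
lowDepthSingletonCalls <- function(callset, truth, pileup, max_depth = 10,
                                   min_gq = 20) {
  tg <- truthGenotypes(truth)
  het <- gtIsHet(tg) & !is.na(tg)
  singles <- which(rowSums(gtDosage(tg), na.rm = TRUE) == 1 &
                   rowSums(het) == 1)
  carrier <- apply(het[singles, , drop = FALSE], 1, which.max)
  dp <- dpMatrix(pileup)
  tk <- paste0(as.character(seqnames(rowRanges(truth))), ":",
               start(rowRanges(truth)))
  pk <- paste0(as.character(seqnames(rowRanges(pileup))), ":",
               start(rowRanges(pileup)))
  cd <- dp[cbind(match(tk[singles], pk), carrier)]
  eligible <- cd < max_depth
  k <- .siteKey(callset)
  hit <- match(tk[singles], k)
  called <- logical(length(singles))
  ok <- !is.na(hit)
  if (any(ok)) {
    g <- gtMatrix(callset)[hit[ok], , drop = FALSE]
    gq <- gqMatrix(callset)[hit[ok], , drop = FALSE]
    cj <- match(colnames(truthGenotypes(truth)), colnames(callset))[carrier[ok]]
    gc <- g[cbind(seq_len(nrow(g)), cj)]
    qc <- gq[cbind(seq_len(nrow(g)), cj)]
    called[ok] <- !is.na(gc) & gtIsHet(gc) & !is.na(qc) & qc >= min_gq
  }
  list(n_called = sum(called & eligible), n_eligible = sum(eligible))
}
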