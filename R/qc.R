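#' Per-genotype quality filters
#'
#' The genotype-level filtering ladder, discarding genotypes with more than
#' about 1% estimated error: individual-based calls are set missing when
#' genotype quality is below 20 or genotype depth below 7x; population-based
#' calls when quality is below 20 (their quality depends less on individual
#' depth); LD-refined calls when the posterior ratio between the best and
#' second-best genotype is below 99:1. Filters only ever add missingness,
#' they never change a called genotype.
#'
#' @param callset A [CallSet]; the caller kind selects the policy.
#' @param min_gq,min_depth,min_posterior_ratio Thresholds (defaults 20, 7,
#'   99).
#' @return The call set with filtered genotypes set to `NA`;
#'   `metadata()$n_filtered` records how many cells were newly removed.
#' @export
applyGenotypeFilters <- function(callset, min_gq = 20, min_depth = 7,
                                 min_posterior_ratio = 99) {
  kind <- callerKind(callset)
  gt <- gtMatrix(callset)
  drop <- switch(kind,
    IBC = gqMatrix(callset) < min_gq | dpMatrix(callset) < min_depth,
    PBC = gqMatrix(callset) < min_gq,
    LDC = assay(callset, "PR") < min_posterior_ratio,
    stop("unknown caller kind: ", kind))
  drop[is.na(drop)] <- FALSE
  newly <- sum(drop & !is.na(gt))
  gt[drop] <- NA_integer_
  assay(callset, "GT") <- gt
  metadata(callset)$n_filtered <- newly
  callset
}

#' Heterozygote-excess statistic
#'
#' Signed z-statistic for deviation from Hardy-Weinberg proportions in the
#' direction of heterozygote excess: `(obs_het - exp_het) / sqrt(var)`
#' where the expected count and binomial variance are computed at the
#' sample allele frequency. Positive values mean excess heterozygotes (the
#' signature of many technical artifacts); monomorphic sites return 0.
#'
#' @param n_rr,n_ra,n_aa Genotype counts.
#' @return Signed z statistic.
#' @examples
#' excessHetZ(25, 50, 25)  # exact HWE at f = 0.5 -> 0
#' @export
excessHetZ <- function(n_rr, n_ra, n_aa) {
  n <- n_rr + n_ra + n_aa
  if (n <= 0) stop("no genotypes")
  f <- (n_ra + 2 * n_aa) / (2 * n)
  if (f <= 0 || f >= 1) return(0)
  p_het <- 2 * f * (1 - f)
  (n_ra - n * p_het) / sqrt(n * p_het * (1 - p_het))
}

#' Per-site quality features
#'
#' The feature vector used for site ranking, computed from non-missing
#' genotypes (and the pileup for allele-balance): deviation of the
#' quality-weighted alternate-read fraction from 1/2 among heterozygous
#' carriers, mean depth, mean genotype quality, call rate, the
#' heterozygote-excess statistic and the site quality.
#'
#' @param callset A [CallSet].
#' @param pileup The matching [CohortPileup] (for allele balance); if
#'   omitted the balance feature is 0.
#' @param params A [modelParams()] list.
#' @return `data.frame` with one row per site: `ab_dev`, `mean_depth`,
#'   `mean_gq`, `call_rate`, `het_excess`, `site_qual`.
#' @export
siteFeatures <- function(callset, pileup = NULL, params = modelParams()) {
  gt <- gtMatrix(callset)
  gq <- gqMatrix(callset)
  dp <- dpMatrix(callset)
  S <- nrow(gt)
  het <- gtIsHet(gt)
  ab <- numeric(S)
  if (!is.null(pileup)) {
    key <- paste0(as.character(seqnames(rowRanges(callset))), ":",
                  start(rowRanges(callset)))
    pkey <- paste0(as.character(seqnames(rowRanges(pileup))), ":",
                   start(rowRanges(pileup)))
    rows <- match(key, pkey)
    bm <- pileupBases(pileup)
    qm <- pileupQuals(pileup)
    alt1 <- vapply(altAlleles(callset), `[`, "", 1)
    for (s in seq_len(S)) {
      carriers <- which(!is.na(het[s, ]) & het[s, ])
      if (!length(carriers) || is.na(rows[s])) next
      fr <- vapply(carriers, function(j) {
        b <- strsplit(bm[rows[s], j], "")[[1]]
        if (!length(b)) return(NA_real_)
        q <- utf8ToInt(qm[rows[s], j]) - 33L
        w <- 1 - phredToError(q, params)
        sum(w[b == alt1[s]]) / sum(w)
      }, 0)
      ab[s] <- mean(abs(fr - 0.5), na.rm = TRUE)
      if (is.nan(ab[s])) ab[s] <- 0
    }
  }
  hz <- vapply(seq_len(S), function(s) {
    g <- gt[s, ]
    excessHetZ(sum(g == 0L, na.rm = TRUE),
               sum(het[s, ], na.rm = TRUE),
               sum(!is.na(g) & g != 0L & !het[s, ], na.rm = TRUE))
  }, 0)
  data.frame(ab_dev = ab,
             mean_depth = rowMeans(dp),
             mean_gq = rowMeans(gq, na.rm = TRUE),
             call_rate = rowMeans(!is.na(gt)),
             het_excess = hz,
             site_qual = ifelse(is.na(siteQual(callset)), 0, siteQual(callset)))
}

#' Rank sites with a linear classifier
#'
#' Trains a linear support-vector machine on labelled good and bad sites
#' (in synthetic runs the labels come from the truth set) and scores every
#' site by its signed margin: positive scores look like good training
#' sites. Deterministic for fixed inputs.
#'
#' @param features Feature `data.frame` from [siteFeatures()].
#' @param good,bad Disjoint integer row indexes of training sites.
#' @param cost SVM cost parameter.
#' @return Numeric score per site (positive = good side).
#' @export
rankSites <- function(features, good, bad, cost = 1) {
  if (!length(good) || !length(bad))
    stop("training requires both good and bad examples")
  if (length(intersect(good, bad)))
    stop("training sets must be disjoint")
  x <- as.matrix(features)
  keep <- apply(x, 2, function(col) stats::sd(col[c(good, bad)]) > 0)
  x <- x[, keep, drop = FALSE]
  y <- factor(rep(c("good", "bad"), c(length(good), length(bad))),
              levels = c("bad", "good"))
  fit <- e1071::svm(x[c(good, bad), , drop = FALSE], y, kernel = "linear",
                    cost = cost, scale = TRUE)
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")[, 1]
  if (mean(dv[good]) < mean(dv[bad])) dv <- -dv  # orient good side positive
  unname(dv)
}

#' Select a fixed-size call set
#'
#' Keeps the `K` top-scoring sites, requiring positive scores; ties at the
#' cutoff break by genomic order (lower coordinate first). If fewer than
#' `K` sites score positive, all positive sites are returned with a
#' warning.
#'
#' @param scores Per-site scores (e.g. from [rankSites()]).
#' @param gr Matching `GRanges` (for the genomic-order tie-break).
#' @param K Number of sites to select.
#' @return Integer indexes of the selected sites, in genomic order.
#' @export
selectTopK <- function(scores, gr, K) {
  if (K <= 0) stop("K must be positive")
  if (K > length(scores)) stop("K exceeds the number of sites")
  pos <- which(scores > 0)
  o <- pos[order(-scores[pos], as.integer(as.factor(seqnames(gr)))[pos],
                 start(gr)[pos])]
  if (length(o) < K) {
    warning("only ", length(o), " sites with positive scores; returning all")
    K <- length(o)
  }
  sort(o[seq_len(K)])
}

#' Imputation-quality site filter
#'
#' Removes sites whose estimated imputation R-squared falls below the
#' threshold (default 0.7). Only applicable to LD-refined call sets.
#'
#' @param callset An `"LDC"` [CallSet] with per-site `R2`.
#' @param threshold Minimum R-squared kept (sites with `R2 < threshold`
#'   are dropped).
#' @return The filtered call set.
#' @export
rsqFilter <- function(callset, threshold = 0.7) {
  if (callerKind(callset) != "LDC" || is.null(imputeRsq(callset)))
    stop("R-squared filtering applies to LD-refined call sets only")
  callset[imputeRsq(callset) >= threshold, ]
}
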