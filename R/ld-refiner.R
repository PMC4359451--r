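#' Merge sequencing calls with a chip scaffold into a marker map
#'
#' Builds the ordered marker map over which the LD refiner runs: all
#' sequence markers of the input call set, plus scaffold (chip) markers
#' lying within `flank_window` bp of a target interval. Scaffold markers
#' inside a target are masked: they stay on the map (and are imputed) but
#' contribute no emission, so on-target chip genotypes can serve as an
#' independent quality measure. A scaffold marker at the position of a
#' sequence marker is reconciled by ref/alt identity (the sequence marker
#' is kept; its chip emission is not used, which masks on-target chip
#' markers that were also discovered in sequence); an allele mismatch at a
#' shared position is an error.
#'
#' @param callset A `"PBC"` [CallSet] (biallelic).
#' @param scaffold A `"CHIP"` [CallSet] of chip genotypes, or `NULL`.
#' @param targets `GRanges` of target intervals (required with a scaffold).
#' @param cfg A [hmmConfig()] list (supplies `flank_window`).
#' @return List with `gr` (ordered marker `GRanges` with `REF`, `ALT`,
#'   `source`, `masked`), `seq_rows` and `scaf_rows` (row indexes into the
#'   inputs, `NA` where a marker has no such row).
#' @export
mergeScaffold <- function(callset, scaffold = NULL, targets = NULL,
                          cfg = hmmConfig()) {
  gr_seq <- granges(rowRanges(callset))
  n_seq <- length(gr_seq)
  if (is.null(scaffold) || nrow(scaffold) == 0) {
    gr <- gr_seq
    mcols(gr)$REF <- refAllele(callset)
    mcols(gr)$ALT <- vapply(altAlleles(callset), `[`, "", 1)
    mcols(gr)$source <- rep("sequence", n_seq)
    mcols(gr)$masked <- rep(FALSE, n_seq)
    o <- order(as.factor(seqnames(gr)), start(gr))
    return(list(gr = gr[o], seq_rows = seq_len(n_seq)[o],
                scaf_rows = rep(NA_integer_, n_seq)))
  }
  if (is.null(targets)) stop("targets required when a scaffold is supplied")
  gr_sc <- granges(rowRanges(scaffold))
  near <- IRanges::overlapsAny(
    gr_sc, GenomicRanges::resize(targets,
                                 GenomicRanges::width(targets) + 2 * cfg$flank_window,
                                 fix = "center"))
  inside <- IRanges::overlapsAny(gr_sc, targets)
  sc_keep <- which(near)

  key_seq <- paste0(as.character(seqnames(gr_seq)), ":", start(gr_seq))
  key_sc <- paste0(as.character(seqnames(gr_sc)), ":", start(gr_sc))[sc_keep]
  shared <- match(key_sc, key_seq)
  if (any(!is.na(shared))) {
    i_sc <- sc_keep[!is.na(shared)]
    i_seq <- shared[!is.na(shared)]
    ok <- refAllele(scaffold)[i_sc] == refAllele(callset)[i_seq] &
      vapply(altAlleles(scaffold)[i_sc], `[`, "", 1) ==
        vapply(altAlleles(callset)[i_seq], `[`, "", 1)
    if (!all(ok))
      stop("allele mismatch between scaffold and sequence markers at ",
           paste(key_sc[!is.na(shared)][!ok], collapse = ", "))
    sc_keep <- sc_keep[is.na(shared)]
  }

  gr1 <- gr_seq
  mcols(gr1)$REF <- refAllele(callset)
  mcols(gr1)$ALT <- vapply(altAlleles(callset), `[`, "", 1)
  mcols(gr1)$source <- rep("sequence", n_seq)
  mcols(gr1)$masked <- rep(FALSE, n_seq)
  gr2 <- gr_sc[sc_keep]
  mcols(gr2)$REF <- refAllele(scaffold)[sc_keep]
  mcols(gr2)$ALT <- vapply(altAlleles(scaffold)[sc_keep], `[`, "", 1)
  mcols(gr2)$source <- rep("scaffold", length(sc_keep))
  mcols(gr2)$masked <- inside[sc_keep]
  gr <- c(gr1, gr2)
  seq_rows <- c(seq_len(n_seq), rep(NA_integer_, length(sc_keep)))
  scaf_rows <- c(rep(NA_integer_, n_seq), sc_keep)
  o <- order(as.factor(seqnames(gr)), start(gr))
  list(gr = gr[o], seq_rows = seq_rows[o], scaf_rows = scaf_rows[o])
}

#' Exact posteriors of the haplotype-copying HMM for one sample
#'
#' Forward-backward over the `K^2` ordered-pair state space of a
#' Li-Stephens haplotype-copying model: each of the sample's two haplotypes
#' copies one of `K` template haplotypes, switching templates between
#' adjacent markers with probability `rho` (uniformly over the `K`
#' templates on a switch) and copying each allele with error `eps`.
#' Marker emissions are genotype likelihood triplets.
#'
#' @param L M x 3 matrix of per-marker likelihoods for alt-allele dosage
#'   0, 1, 2 (linear scale; use a flat row for a marker with no data).
#' @param H K x M 0/1 matrix of template haplotypes.
#' @param rho Per-interval switch probability (scalar or length `M-1`).
#' @param eps Per-allele copying error (scalar or per-marker vector).
#' @param sample_path Also draw one path and allele pair from the
#'   posterior (uses the R RNG).
#' @return List with `post` (M x 3 exact marginal dosage posteriors),
#'   `hap` (2 x M sampled haplotypes, if requested), `switches`,
#'   `mismatches` and `loglik`.
#' @export
lsHmmPosterior <- function(L, H, rho, eps, sample_path = FALSE) {
  L <- as.matrix(L)
  H <- as.matrix(H)
  M <- nrow(L)
  if (length(rho) == 1) rho <- rep(rho, max(M - 1, 0))
  if (length(eps) == 1) eps <- rep(eps, M)
  storage.mode(H) <- "integer"
  cpp_lshmm_sample(L, H, as.numeric(rho), as.numeric(eps), sample_path,
                   greedy_alleles = FALSE)
}

## emission triplet matrices (M x 3 per sample, linear scale) for a marker map
.refinerTriplets <- function(map, callset, scaffold, chip_error) {
  M <- length(map$gr)
  N <- ncol(callset)
  L1 <- matrix(1, M, N); L2 <- matrix(1, M, N); L3 <- matrix(1, M, N)
  is_seq <- !is.na(map$seq_rows)
  if (any(is_seq)) {
    r <- map$seq_rows[is_seq]
    L1[is_seq, ] <- exp(assay(callset, "LRR")[r, , drop = FALSE])
    L2[is_seq, ] <- exp(assay(callset, "LRA")[r, , drop = FALSE])
    L3[is_seq, ] <- exp(assay(callset, "LAA")[r, , drop = FALSE])
  }
  is_sc <- !is.na(map$scaf_rows) & !mcols(map$gr)$masked
  if (any(is_sc) && !is.null(scaffold)) {
    g <- gtMatrix(scaffold)[map$scaf_rows[is_sc],
                            match(colnames(callset), colnames(scaffold)),
                            drop = FALSE]
    d <- gtDosage(g)
    e <- chip_error
    for (dd in 0:2) {
      hit <- !is.na(d) & d == dd
      L1[is_sc, ][hit] <- if (dd == 0) 1 - e else e / 2
      L2[is_sc, ][hit] <- if (dd == 1) 1 - e else e / 2
      L3[is_sc, ][hit] <- if (dd == 2) 1 - e else e / 2
    }
  }
  list(L1 = L1, L2 = L2, L3 = L3)
}

#' LD-aware genotype refinement
#'
#' Iterative haplotype-copying refinement of a population-based call set,
#' optionally extended with chip genotypes at flanking markers. Starting
#' from randomly phased best-guess genotypes, each iteration visits the
#' samples in random order, runs the exact forward-backward of
#' [lsHmmPosterior()] against `K` template haplotypes sampled from the
#' other samples' current panel, samples a new haplotype pair for the
#' sample, and re-estimates the copying error and per-interval switch
#' rates from the sampled mismatch and switch counts. Marginal dosage
#' posteriors are averaged over post-burn-in iterations.
#'
#' @param callset A `"PBC"` [CallSet] with likelihood-triplet assays.
#' @param scaffold Optional `"CHIP"` [CallSet] of chip genotypes.
#' @param targets `GRanges` of target intervals (needed with a scaffold).
#' @param cfg A [hmmConfig()] list.
#' @param params A [modelParams()] list (posterior threshold for GQ).
#' @return A [CallSet] (caller `"LDC"`) over the same sites as the input,
#'   with assays `GT` (argmax of the averaged posterior), `GQ`, `DP`,
#'   dosage `DS`, posterior triplets `PRR`/`PRA`/`PAA` and the
#'   best-to-second posterior ratio `PR`; per-site `R2` is the estimated
#'   imputation quality (see [estimateRsq()]).
#' @export
refineLD <- function(callset, scaffold = NULL, targets = NULL,
                     cfg = hmmConfig(), params = modelParams()) {
  if (callerKind(callset) != "PBC")
    stop("refineLD expects a population-based call set")
  N <- ncol(callset)
  map <- mergeScaffold(callset, scaffold, targets, cfg)
  M <- length(map$gr)
  af <- alleleFreq(callset)

  if (N < 2) {
    ## degenerate panel: no reference haplotypes; return PBC posteriors
    tri <- .refinerTriplets(map, callset, scaffold, cfg$chip_error)
    sr <- !is.na(map$seq_rows)
    idx <- map$seq_rows[sr]
    p0 <- tri$L1[sr, , drop = FALSE] * (1 - af[idx])^2
    p1 <- tri$L2[sr, , drop = FALSE] * 2 * af[idx] * (1 - af[idx])
    p2 <- tri$L3[sr, , drop = FALSE] * af[idx]^2
    tot <- p0 + p1 + p2
    return(.refinedCallset(callset, p0[order(idx), , drop = FALSE] / tot[order(idx), , drop = FALSE],
                           p1[order(idx), , drop = FALSE] / tot[order(idx), , drop = FALSE],
                           p2[order(idx), , drop = FALSE] / tot[order(idx), , drop = FALSE],
                           params, cfg))
  }

  tri <- .refinerTriplets(map, callset, scaffold, cfg$chip_error)

  ## initial panel: randomly phased best-guess genotypes; flat cells drawn
  ## from the site frequency
  fmap <- rowMeans(tri$L2 / (tri$L1 + tri$L2 + tri$L3))  # crude, only for flats
  fmap[!is.na(map$seq_rows)] <- af[map$seq_rows[!is.na(map$seq_rows)]]
  H <- matrix(0L, 2 * N, M)
  for (i in seq_len(N)) {
    w0 <- tri$L1[, i]; w1 <- tri$L2[, i]; w2 <- tri$L3[, i]
    flat <- w0 == w1 & w1 == w2
    d <- max.col(cbind(w0, w1, w2), ties.method = "first") - 1L
    h1 <- as.integer(d == 2L)
    h2 <- h1
    het <- d == 1L
    coin <- stats::runif(sum(het)) < 0.5
    h1[het] <- as.integer(coin)
    h2[het] <- as.integer(!coin)
    if (any(flat)) {
      h1[flat] <- stats::rbinom(sum(flat), 1L, pmin(pmax(fmap[flat], 1e-3), 0.999))
      h2[flat] <- stats::rbinom(sum(flat), 1L, pmin(pmax(fmap[flat], 1e-3), 0.999))
    }
    H[2 * i - 1, ] <- h1
    H[2 * i, ] <- h2
  }

  eps <- rep(cfg$error_rate, M)       # per-marker copying error
  rho <- rep(cfg$crossover_rate, max(M - 1, 0))
  K <- min(cfg$n_reference_haplotypes, 2 * (N - 1))
  post_sum <- array(0, dim = c(M, 3, N))
  n_avg <- 0L
  Lbuf <- matrix(0, M, 3)

  for (it in seq_len(cfg$n_iterations)) {
    mism <- numeric(M)
    sw <- numeric(max(M - 1, 0))
    for (i in sample.int(N)) {
      pool <- setdiff(seq_len(2 * N), c(2 * i - 1, 2 * i))
      sel <- pool[sample.int(length(pool), K)]
      Lbuf[, 1] <- tri$L1[, i]; Lbuf[, 2] <- tri$L2[, i]; Lbuf[, 3] <- tri$L3[, i]
      res <- cpp_lshmm_sample(Lbuf, H[sel, , drop = FALSE], rho, eps, TRUE,
                              greedy_alleles = TRUE)
      H[2 * i - 1, ] <- res$hap[1, ]
      H[2 * i, ] <- res$hap[2, ]
      mism <- mism + res$mismatches
      if (M > 1) sw <- sw + res$switches
      if (it > cfg$burn_in) post_sum[, , i] <- post_sum[, , i] + res$post
    }
    if (it > cfg$burn_in) n_avg <- n_avg + 1L
    ## per-marker copying error: residual mismatch rate not already explained
    ## by the panel allele frequency (recent mutations sit on the panel once;
    ## counting them again through eps would double the implied het rate)
    panel_f <- colMeans(H)
    panel_f <- pmin(panel_f, 1 - panel_f)
    eps <- pmin(pmax(mism / (2 * N) - panel_f, 2e-4), 0.2)
    if (M > 1) {
      adj <- 1 - 1 / K
      rho <- pmin(pmax((sw / (2 * N)) / adj, 1e-5), 0.45)
    }
  }

  post <- post_sum / n_avg
  sr <- which(!is.na(map$seq_rows))
  rows <- sr[order(map$seq_rows[sr])]  # map rows in original site order
  out <- .refinedCallset(callset,
                         matrix(post[rows, 1, ], length(rows)),
                         matrix(post[rows, 2, ], length(rows)),
                         matrix(post[rows, 3, ], length(rows)),
                         params, cfg)
  metadata(out)$hmm_eps <- eps
  metadata(out)$hmm_rho <- rho
  out
}

## assemble the LDC CallSet from per-cell posterior triplets (sites x samples)
.refinedCallset <- function(callset, p0, p1, p2, params, cfg) {
  pbest <- pmax(p0, p1, p2)
  best <- ifelse(p0 == pbest, 0L, ifelse(p1 == pbest, 1L, 2L))
  psec <- (p0 + p1 + p2) - pbest - pmin(p0, p1, p2)  # middle value
  ratio <- pbest / pmax(psec, 1e-12)
  ds <- p1 + 2 * p2
  gt <- ifelse(best == 2L, 11L, best)
  gq <- pmin(-10 * log10(pmax(1 - pbest, 1e-10)), 100)
  rsq <- if (ncol(ds) >= 2) apply(ds, 1, estimateRsq) else rep(NA_real_, nrow(ds))
  cs <- callSet(granges(rowRanges(callset)), ref = refAllele(callset),
                alt = as.list(vapply(altAlleles(callset), `[`, "", 1)),
                assays = list(GT = gt, GQ = gq, DP = dpMatrix(callset),
                              DS = ds, PRR = p0, PRA = p1, PAA = p2,
                              PR = ratio),
                samples = colnames(callset), caller = "LDC",
                qual = siteQual(callset), af = rowMeans(ds) / 2,
                rsq = rsq, params = params, hmm = cfg)
  cs
}

#' Imputation quality R-squared
#'
#' Ratio of the variance of the estimated allele dosages to the binomial
#' variance expected at the estimated frequency,
#' `Var(dosage) / (2*fbar*(1-fbar))` with `fbar = mean(dosage)/2`
#' (population variance), clamped to `[0, 1]`; 0 when `fbar` is 0 or 1.
#' Hardened posteriors at a site in Hardy-Weinberg give values near 1,
#' uninformative (shrunken) dosages give values near 0.
#'
#' @param dosages Per-sample alt-allele dosages at one site (length >= 2).
#' @return R-squared estimate in `[0, 1]`.
#' @examples
#' estimateRsq(c(0, 0, 1, 1))  # 0.6667
#' @export
estimateRsq <- function(dosages) {
  if (length(dosages) < 2) stop("need at least 2 samples")
  fbar <- mean(dosages) / 2
  if (fbar <= 0 || fbar >= 1) return(0)
  v <- mean((dosages - mean(dosages))^2)
  min(max(v / (2 * fbar * (1 - fbar)), 0), 1)
}
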