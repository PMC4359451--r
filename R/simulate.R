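#' Draw allele counts from a site frequency spectrum
#'
#' Samples the alternate-allele count of a segregating site in a sample of
#' `n_chromosomes` chromosomes. With `xi = 1` (default) this is the
#' stationary neutral site frequency spectrum, `P(count = i)` proportional
#' to `1/i` for `i` in `1..n-1`; larger `xi` gives the rare-variant excess
#' typical of exonic cohorts.
#'
#' @param n_chromosomes Number of chromosomes (>= 2).
#' @param n Number of draws.
#' @param xi Spectrum exponent (`P(i)` proportional to `i^-xi`).
#' @return Integer allele counts in `1..(n_chromosomes - 1)`.
#' @examples
#' set.seed(1)
#' table(sfsFrequencyDraw(4, 1000)) / 1000  # ~ (0.545, 0.273, 0.182)
#' @export
sfsFrequencyDraw <- function(n_chromosomes, n = 1, xi = 1) {
  if (n_chromosomes < 2) stop("need at least 2 chromosomes")
  i <- seq_len(n_chromosomes - 1)
  sample.int(n_chromosomes - 1, n, replace = TRUE, prob = i^(-xi))
}

## founder-mosaic walk: founder index per marker for one chromosome,
## with per-interval switch probabilities
.mosaicPath <- function(n_markers, switch_probs, founders) {
  sw <- c(TRUE, stats::runif(n_markers - 1) < switch_probs)
  seg <- cumsum(sw)
  sample.int(founders, max(seg), replace = TRUE)[seg]
}

#' Simulate cohort haplotypes with LD and a rare-variant-heavy spectrum
#'
#' Builds the true haplotypes of a synthetic targeted-sequencing cohort.
#' Common variants (frequency at or above `common_threshold`) are placed on
#' `founders` founder haplotypes; each sample chromosome is a founder
#' mosaic with per-bp template switch rate `switch_rate`, which creates
#' tunable linkage disequilibrium between common markers (including the
#' chip-like flanking markers placed within `flank_window` of each target).
#' Rare variants are assigned directly to individual chromosomes at their
#' drawn allele counts, emulating recent mutations that do not ride the
#' founder structure.
#'
#' @param cfg A [simConfig()] list. Uses the current RNG state; seed it (or
#'   call via [simulateCohort()], which seeds from `cfg$seed`).
#' @return List with `map` (marker `GRanges` with `REF`, `ALT`, `af`
#'   realised frequency, `count`, `is_variant`, `is_artifact`,
#'   `on_target`, `founder_borne`), `haplotypes` (2n x markers 0/1
#'   matrix), `targets` (`GRanges` of target intervals) and `founders`.
#' @export
simulateHaplotypes <- function(cfg) {
  nu <- cfg$n_samples
  nchr <- 2L * nu
  chrom <- "chr1"
  gene_start <- 1e6 + (seq_len(cfg$n_genes) - 1) * (2 * cfg$flank_window +
                                                    cfg$gene_span + 1e6)
  targets <- GRanges(chrom, IRanges(gene_start, width = cfg$gene_span))

  ## --- on-target candidate sites ------------------------------------------
  per_gene <- diff(round(seq(0, cfg$n_target_sites, length.out = cfg$n_genes + 1)))
  pos <- unlist(lapply(seq_len(cfg$n_genes), function(g)
    sort(sample.int(cfg$gene_span, per_gene[g]) + gene_start[g] - 1L)))
  counts <- sfsFrequencyDraw(nchr, length(pos), xi = cfg$sfs_xi)

  n_extra <- length(cfg$extra_count_sites)
  if (n_extra) {
    pool <- setdiff(seq_len(cfg$gene_span) + gene_start[1] - 1L, pos)
    pos <- c(pos, sort(sample(pool, n_extra)))
    counts <- c(counts, pmin(pmax(cfg$extra_count_sites, 1L), nchr - 1L))
  }
  n_art <- round(cfg$artifact_fraction * cfg$n_target_sites)
  if (n_art) {
    pool <- setdiff(seq_len(cfg$gene_span) + gene_start[min(2, cfg$n_genes)] - 1L, pos)
    pos <- c(pos, sort(sample(pool, n_art)))
    counts <- c(counts, rep(0L, n_art))
  }
  is_extra <- c(rep(FALSE, length(pos) - n_extra - n_art),
                rep(TRUE, n_extra), rep(FALSE, n_art))
  o <- order(pos)
  pos <- pos[o]
  counts <- counts[o]
  is_extra <- is_extra[o]
  is_artifact <- counts == 0L
  S <- length(pos)

  ref <- sample(.ALLELES, S, replace = TRUE)
  alt <- vapply(seq_len(S), function(s) {
    r <- ref[s]
    trs <- switch(r, A = "G", G = "A", C = "T", T = "C")
    tvs <- setdiff(.ALLELES, c(r, trs))
    if (stats::runif(1) < cfg$ts_bias) trs else sample(tvs, 1)
  }, "")

  freq <- counts / nchr
  ## explicit-count sites are always assigned directly so their realised
  ## counts are exact
  common <- !is_artifact & !is_extra & freq >= cfg$common_threshold

  ## --- flanking chip markers (always common, founder-borne) ----------------
  nf <- cfg$n_flank_markers
  fl_pos <- integer(0)
  if (nf > 0) {
    per_gene_f <- diff(round(seq(0, nf, length.out = cfg$n_genes + 1)))
    fl_pos <- unlist(lapply(seq_len(cfg$n_genes), function(g) {
      win <- c((gene_start[g] - cfg$flank_window):(gene_start[g] - 1L),
               (gene_start[g] + cfg$gene_span):(gene_start[g] + cfg$gene_span +
                                                cfg$flank_window - 1L))
      sort(sample(win, per_gene_f[g]))
    }))
  }
  fl_ref <- sample(.ALLELES, length(fl_pos), replace = TRUE)
  fl_alt <- vapply(fl_ref, function(r)
    sample(setdiff(.ALLELES, r), 1), "")
  fl_freq <- stats::runif(length(fl_pos), cfg$common_threshold, 0.5)

  ## --- founder haplotypes over the founder-borne markers -------------------
  fb_pos <- c(pos[common], fl_pos)
  fb_freq <- c(freq[common], fl_freq)
  fb_o <- order(fb_pos)
  fb_pos <- fb_pos[fb_o]
  fb_freq <- fb_freq[fb_o]
  Mf <- length(fb_pos)
  Ffound <- matrix(0L, cfg$founders, Mf)
  for (m in seq_len(Mf)) {
    k <- max(1L, min(cfg$founders - 1L, round(cfg$founders * fb_freq[m])))
    Ffound[sample.int(cfg$founders, k), m] <- 1L
  }

  ## --- sample chromosomes: mosaics + rare overlay --------------------------
  switch_probs <- if (Mf > 1) {
    pmin(1 - exp(-cfg$switch_rate * diff(fb_pos)), 0.5)
  } else numeric(0)
  hap_fb <- matrix(0L, nchr, Mf)
  paths <- matrix(0L, nchr, Mf)          # founder identity per chromosome
  for (h in seq_len(nchr)) {
    if (Mf == 0) break
    path <- .mosaicPath(Mf, switch_probs, cfg$founders)
    paths[h, ] <- path
    hap_fb[h, ] <- Ffound[cbind(path, seq_len(Mf))]
  }

  ## full marker map = on-target sites + flank markers, position-sorted
  all_pos <- c(pos, fl_pos)
  all_ref <- c(ref, fl_ref)
  all_alt <- c(alt, fl_alt)
  on_target <- c(rep(TRUE, S), rep(FALSE, length(fl_pos)))
  art_all <- c(is_artifact, rep(FALSE, length(fl_pos)))
  fb_all <- c(common, rep(TRUE, length(fl_pos)))
  ao <- order(all_pos)
  all_pos <- all_pos[ao]; all_ref <- all_ref[ao]; all_alt <- all_alt[ao]
  on_target <- on_target[ao]; art_all <- art_all[ao]; fb_all <- fb_all[ao]
  counts_all <- c(counts, round(fl_freq * nchr))[ao]

  M <- length(all_pos)
  hap <- matrix(0L, nchr, M)
  hap[, fb_all] <- hap_fb[, match(all_pos[fb_all], fb_pos), drop = FALSE]
  ## rare variants are recent mutations: they arise on one founder background
  ## (the founder segment of a randomly chosen anchor chromosome at the
  ## nearest founder-borne marker) and their carriers share that background
  rare <- which(!fb_all & !art_all & counts_all > 0)
  for (m in rare) {
    c_m <- counts_all[m]
    if (Mf > 0) {
      nearest <- which.min(abs(fb_pos - all_pos[m]))
      anchor <- paths[sample.int(nchr, 1), nearest]
      eligible <- which(paths[, nearest] == anchor)
      carriers <- eligible[sample.int(length(eligible),
                                      min(c_m, length(eligible)))]
      extra <- c_m - length(carriers)
      if (extra > 0)
        carriers <- c(carriers,
                      sample(setdiff(seq_len(nchr), carriers), extra))
    } else {
      carriers <- sample.int(nchr, c_m)
    }
    hap[carriers, m] <- 1L
  }

  af <- colSums(hap) / nchr
  gr <- GRanges("chr1", IRanges(all_pos, width = 1L))
  mcols(gr)$REF <- all_ref
  mcols(gr)$ALT <- all_alt
  mcols(gr)$af <- af
  mcols(gr)$count <- as.integer(colSums(hap))
  mcols(gr)$is_variant <- af > 0 & !art_all
  mcols(gr)$is_artifact <- art_all
  mcols(gr)$on_target <- on_target
  mcols(gr)$founder_borne <- fb_all
  list(map = gr, haplotypes = hap, targets = targets, founders = Ffound)
}

#' Simulate sequencing reads for a cohort
#'
#' Generates per-site per-sample reads with heterogeneous capture depth:
#' depth is Poisson with mean `mean_depth * a_j * b_s`, where `a_j`
#' (per sample) and `b_s` (per site) are unit-mean gamma factors. Each
#' read draws one of the two genotype alleles uniformly, is assigned a
#' PHRED quality from the configured distribution and is flipped to a
#' uniformly chosen other base with the corresponding error probability.
#' At artifact sites, half the samples (in expectation) receive
#' contaminated reads that mimic a spurious heterozygote.
#'
#' @param genotypes Sites x samples matrix of genotype codes (0/1/11).
#' @param map Marker `GRanges` (rows matching `genotypes`) with `REF`,
#'   `ALT`, `is_artifact`.
#' @param samples Sample ids (columns).
#' @param cfg A [simConfig()] list. Uses the current RNG state.
#' @return A [CohortPileup].
#' @export
simulateReads <- function(genotypes, map, samples, cfg) {
  S <- nrow(genotypes)
  N <- ncol(genotypes)
  a <- stats::rgamma(N, cfg$sample_disp_shape, cfg$sample_disp_shape)
  b <- stats::rgamma(S, cfg$site_disp_shape, cfg$site_disp_shape)
  refc <- match(mcols(map)$REF, .ALLELES) - 1L
  altc <- match(mcols(map)$ALT, .ALLELES) - 1L
  is_art <- mcols(map)$is_artifact
  dose <- gtDosage(genotypes)

  codes <- vector("list", S)
  phred <- vector("list", S)
  lens <- matrix(0L, S, N)
  for (s in seq_len(S)) {
    d <- stats::rpois(N, cfg$mean_depth * a * b[s])
    lens[s, ] <- d
    Tn <- sum(d)
    if (Tn == 0) { codes[[s]] <- integer(); phred[[s]] <- integer(); next }
    cell <- rep.int(seq_len(N), d)
    p_alt <- dose[s, cell] / 2
    if (is_art[s]) {
      contam <- stats::runif(N) < 0.5
      p_alt <- ifelse(contam[cell], 0.35, p_alt)
    }
    is_alt <- stats::runif(Tn) < p_alt
    base <- ifelse(is_alt, altc[s], refc[s])
    q <- cfg$qual_values[sample.int(length(cfg$qual_values), Tn,
                                    replace = TRUE, prob = cfg$qual_probs)]
    err <- stats::runif(Tn) < 10^(-q / 10)
    if (any(err)) {
      shift <- sample.int(3, sum(err), replace = TRUE)
      base[err] <- (base[err] + shift) %% 4L
    }
    codes[[s]] <- as.integer(base)
    phred[[s]] <- as.integer(q)
  }
  enc <- cpp_encode_reads(unlist(codes), unlist(phred), as.integer(t(lens)))
  bases <- matrix(enc$bases, S, N, byrow = TRUE)
  quals <- matrix(enc$quals, S, N, byrow = TRUE)
  cohortPileup(as.character(seqnames(map)), start(map), mcols(map)$REF,
               samples, bases, quals)
}

#' Simulate a full synthetic cohort
#'
#' Composes haplotype simulation, read generation, replicate pairs, the
#' chip scaffold and the known-site list into an end-to-end fixture with
#' complete truth tracking. Replicate individuals appear as extra columns
#' (ids `<sample>_rep`) with identical true genotypes but independently
#' regenerated reads and an independent per-sample depth factor; chip
#' genotypes are the truth perturbed at the chip error rate, restricted to
#' common founder-borne markers (flanking markers plus common on-target
#' sites); the known-site list contains true variants at or above
#' `known_freq`. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [simConfig()] list.
#' @return List with `pileup` ([CohortPileup], on-target sites, all
#'   columns), `scaffold` (`"CHIP"` [CallSet]), `known`
#'   (`data.frame(chrom, pos, alt)`), `truth` ([TruthSet]), `targets`
#'   (`GRanges`) and `config`.
#' @export
simulateCohort <- function(cfg) {
  set.seed(cfg$seed)
  hs <- simulateHaplotypes(cfg)
  nu <- cfg$n_samples
  base_ids <- sprintf("S%04d", seq_len(nu))
  rep_of <- sort(sample.int(nu, cfg$n_replicate_pairs))
  rep_ids <- if (length(rep_of)) paste0(base_ids[rep_of], "_rep") else character(0)
  all_ids <- c(base_ids, rep_ids)

  ## true genotypes per individual over the full map
  d1 <- hs$haplotypes[seq(1, 2 * nu, by = 2), , drop = FALSE]
  d2 <- hs$haplotypes[seq(2, 2 * nu, by = 2), , drop = FALSE]
  dose <- t(d1 + d2)                       # markers x individuals
  gt_all <- matrix(ifelse(dose == 2, 11L, dose), nrow(dose), nu)
  gt_all <- cbind(gt_all, gt_all[, rep_of, drop = FALSE])
  colnames(gt_all) <- all_ids

  map <- hs$map
  ot <- mcols(map)$on_target
  pileup <- simulateReads(gt_all[ot, , drop = FALSE], map[ot], all_ids, cfg)

  ## chip scaffold: flanking markers + common on-target markers
  chip_rows <- which(mcols(map)$founder_borne &
                     (!ot | mcols(map)$af >= cfg$common_threshold))
  chip_gt_u <- gt_all[chip_rows, seq_len(nu), drop = FALSE]
  flip <- which(stats::runif(length(chip_gt_u)) < cfg$chip_error)
  for (i in flip) {
    others <- setdiff(c(0L, 1L, 11L), chip_gt_u[i])
    chip_gt_u[i] <- sample(others, 1)
  }
  chip_gt <- cbind(chip_gt_u, chip_gt_u[, rep_of, drop = FALSE])
  colnames(chip_gt) <- all_ids
  scaffold <- callSet(granges(map[chip_rows]),
                      ref = mcols(map)$REF[chip_rows],
                      alt = as.list(mcols(map)$ALT[chip_rows]),
                      assays = list(GT = chip_gt),
                      samples = all_ids, caller = "CHIP",
                      af = mcols(map)$af[chip_rows])

  kn <- which(ot & mcols(map)$is_variant & mcols(map)$af >= cfg$known_freq)
  known <- data.frame(chrom = as.character(seqnames(map))[kn],
                      pos = start(map)[kn],
                      alt = mcols(map)$ALT[kn])

  tr_gr <- map[ot]
  truth <- new("TruthSet", rowRanges = tr_gr,
               genotypes = gt_all[ot, , drop = FALSE],
               pairs = data.frame(sample = base_ids[rep_of],
                                  replicate = rep_ids,
                                  stringsAsFactors = FALSE))
  list(pileup = pileup, scaffold = scaffold, known = known, truth = truth,
       targets = hs$targets, config = cfg)
}
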