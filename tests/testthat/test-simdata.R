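test_that("the neutral SFS draw matches its normalised weights", {
  # n = 4 chromosomes: P(1) = 1/(1 + 1/2 + 1/3) = 0.5454...
  set.seed(21)
  draws <- sfsFrequencyDraw(4, 2e4)
  p1 <- mean(draws == 1)
  expect_lt(abs(p1 - 6 / 11), 3 * sqrt(6 / 11 * 5 / 11 / 2e4))
  # n = 2: always count 1
  expect_true(all(sfsFrequencyDraw(2, 50) == 1))
  # Monte-Carlo mean against the closed form, 1e5 draws
  n <- 30
  i <- 1:(n - 1)
  p <- (1 / i) / sum(1 / i)
  mu <- sum(i * p)
  sdv <- sqrt(sum(i^2 * p) - mu^2)
  draws2 <- sfsFrequencyDraw(n, 1e5)
  expect_lt(abs(mean(draws2) - mu), 3 * sdv / sqrt(1e5))
  expect_error(sfsFrequencyDraw(1), "chromosomes")
})

test_that("zero switching makes every sample haplotype a founder copy", {
  cfg <- simConfig(n_samples = 30, n_target_sites = 80, n_flank_markers = 20,
                   switch_rate = 0, sfs_xi = 0.5, n_replicate_pairs = 0,
                   seed = 61)
  set.seed(cfg$seed)
  hs <- simulateHaplotypes(cfg)
  fb <- S4Vectors::mcols(hs$map)$founder_borne
  expect_gt(sum(fb), 5)
  hap_fb <- hs$haplotypes[, fb, drop = FALSE]
  founder_rows <- apply(hs$founders, 1, paste, collapse = "")
  # restrict founders to the same marker order as the map
  for (h in sample(nrow(hap_fb), 10))
    expect_true(paste(hap_fb[h, ], collapse = "") %in%
                  apply(hs$founders[, match(
                    GenomicRanges::start(hs$map)[fb],
                    sort(GenomicRanges::start(hs$map)[fb])), drop = FALSE],
                    1, paste, collapse = ""))
})

test_that("adjacent-marker LD decreases as the mosaic switch rate grows", {
  r2adj <- function(sw) {
    cfg <- simConfig(n_samples = 120, n_target_sites = 150,
                     n_flank_markers = 0, switch_rate = sw, sfs_xi = 0.3,
                     n_replicate_pairs = 0, seed = 62)
    set.seed(cfg$seed)
    hs <- simulateHaplotypes(cfg)
    fb <- which(S4Vectors::mcols(hs$map)$founder_borne)
    h <- hs$haplotypes
    mean(vapply(seq_len(length(fb) - 1), function(i) {
      a <- h[, fb[i]]; b <- h[, fb[i + 1]]
      if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
      cor(a, b)^2
    }, 0), na.rm = TRUE)
  }
  vals <- c(r2adj(0), r2adj(2e-5), r2adj(2e-3))
  expect_true(all(diff(vals) < 0))
})

test_that("cohorts are reproducible and replicates share truth but not reads", {
  cfg <- simConfig(n_samples = 25, n_target_sites = 50, n_flank_markers = 10,
                   n_replicate_pairs = 3, seed = 63)
  sim1 <- simulateCohort(cfg)
  sim2 <- simulateCohort(cfg)
  expect_identical(pileupBases(sim1$pileup), pileupBases(sim2$pileup))
  expect_identical(truthGenotypes(sim1$truth), truthGenotypes(sim2$truth))

  pairs <- replicatePairs(sim1$truth)
  expect_equal(nrow(pairs), 3)
  tg <- truthGenotypes(sim1$truth)
  for (p in seq_len(3)) {
    expect_identical(tg[, pairs$sample[p]], tg[, pairs$replicate[p]])
    expect_false(identical(pileupBases(sim1$pileup)[, pairs$sample[p]],
                           pileupBases(sim1$pileup)[, pairs$replicate[p]]))
  }
})

test_that("chip scaffold concordance reflects the configured error rate", {
  cfg <- simConfig(n_samples = 150, n_target_sites = 200,
                   n_flank_markers = 60, chip_error = 0.02,
                   n_replicate_pairs = 0, seed = 64)
  sim <- simulateCohort(cfg)
  chip <- gtMatrix(sim$scaffold)
  tk <- paste0("chr1:", start(rowRanges(sim$truth)))
  ck <- paste0("chr1:", start(rowRanges(sim$scaffold)))
  m <- match(ck, tk)
  ot <- !is.na(m)
  conc <- mean(chip[ot, ] == truthGenotypes(sim$truth)[m[ot], ])
  n <- sum(ot) * ncol(chip)
  expect_lt(abs(conc - 0.98), 3 * sqrt(0.98 * 0.02 / n) + 0.002)
})

test_that("read generation respects depth, error and quality settings", {
  # no errors possible at infinite quality: reads carry genotype alleles only
  cfg <- simConfig(n_samples = 20, n_target_sites = 30, n_flank_markers = 0,
                   qual_values = 93L, qual_probs = 1, n_replicate_pairs = 0,
                   seed = 65)
  sim <- simulateCohort(cfg)
  tg <- truthGenotypes(sim$truth)
  bm <- pileupBases(sim$pileup)
  ref <- refAllele(sim$pileup)
  alt <- vapply(seq_len(nrow(tg)), function(s)
    S4Vectors::mcols(rowRanges(sim$truth))$ALT[s], "")
  for (s in seq_len(nrow(tg))) for (j in seq_len(ncol(tg))) {
    obs <- unique(strsplit(bm[s, j], "")[[1]])
    allowed <- c(ref[s], alt[s])[c(TRUE, gtDosage(tg[s, j]) > 0)]
    expect_true(all(obs %in% allowed))
  }

  # realised mean depth within 2% of the configured mean on >= 1e5 cells
  cfg2 <- simConfig(n_samples = 120, n_target_sites = 900,
                    n_flank_markers = 0, n_replicate_pairs = 0, seed = 66)
  sim2 <- simulateCohort(cfg2)
  d <- dpMatrix(sim2$pileup)
  expect_gt(length(d), 1e5)
  expect_lt(abs(mean(d) / cfg2$mean_depth - 1), 0.02)
  # heterogeneous capture: per-cell depth spans 0 to beyond 3x the mean
  expect_true(any(d == 0))
  expect_gt(max(d), 3 * cfg2$mean_depth)
})

test_that("the generated spectrum is singleton-heavy among segregating sites", {
  cfg <- simConfig(n_samples = 500, n_target_sites = 1200,
                   n_flank_markers = 0, n_replicate_pairs = 0, seed = 67)
  set.seed(cfg$seed)
  hs <- simulateHaplotypes(cfg)
  m <- S4Vectors::mcols(hs$map)
  seg <- m$count > 0 & !m$is_artifact
  expect_gt(mean(m$count[seg] == 1), 0.40)
})

test_that("common-site genotype counts are consistent with Hardy-Weinberg", {
  cfg <- simConfig(n_samples = 400, n_target_sites = 400,
                   n_flank_markers = 0, n_replicate_pairs = 0, seed = 68)
  sim <- simulateCohort(cfg)
  tg <- truthGenotypes(sim$truth)
  af <- S4Vectors::mcols(rowRanges(sim$truth))$af
  common <- which(af >= 0.05 & af <= 0.95)
  pvals <- vapply(common, function(s) {
    counts <- c(sum(tg[s, ] == 0L), sum(tg[s, ] == 1L), sum(tg[s, ] == 11L))
    f <- (counts[2] + 2 * counts[3]) / (2 * sum(counts))
    expd <- sum(counts) * c((1 - f)^2, 2 * f * (1 - f), f^2)
    suppressWarnings(chisq.test(counts, p = expd / sum(expd))$p.value)
  }, 0)
  expect_gt(mean(pvals > 0.001), 0.99)
})

test_that("explicit-count sites carry exactly the requested allele counts", {
  cfg <- simConfig(n_samples = 100, n_target_sites = 50, n_flank_markers = 0,
                   n_replicate_pairs = 0, extra_count_sites = c(1L, 10L, 100L),
                   seed = 69)
  sim <- simulateCohort(cfg)
  counts <- S4Vectors::mcols(rowRanges(sim$truth))$count
  expect_true(all(c(1L, 10L, 100L) %in% counts))
})
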