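test_that("forward-backward marginals match brute-force path enumeration", {
  set.seed(3)
  for (rep in 1:12) {
    M <- sample(1:3, 1)
    K <- sample(1:3, 1)
    L <- matrix(runif(M * 3), M, 3)
    H <- matrix(rbinom(K * M, 1, 0.5), K, M)
    rho <- runif(max(M - 1, 0), 0.01, 0.4)
    eps <- runif(1, 0.005, 0.2)
    got <- lsHmmPosterior(L, H, rho, eps)$post
    want <- enumLsHmm(L, H, rho, eps)
    expect_equal(got, want, tolerance = 1e-10)
    expect_equal(rowSums(got), rep(1, M), tolerance = 1e-12)
  }
})

test_that("a single template with no data forces its implied genotype", {
  # K = 1, rho -> 0, eps -> 0: the posterior concentrates on the template
  M <- 4
  H <- matrix(c(0L, 1L, 1L, 0L), 1, M)
  L <- matrix(1, M, 3)                       # no read data
  post <- lsHmmPosterior(L, H, rep(1e-9, M - 1), 1e-6)$post
  implied <- 2 * H[1, ]                      # both haplotypes copy the template
  expect_equal(apply(post, 1, which.max) - 1L, implied + 0L)
  expect_true(all(post[cbind(1:M, implied + 1L)] > 0.999))
})

test_that("overwhelming read evidence dominates the template prior", {
  gl <- exp(genotypeLikelihoods(c(rep("A", 12), rep("G", 12)),
                                rep(30, 24))$loglik[c("AA", "AG", "GG")])
  M <- 3
  L <- rbind(c(1, 1, 1), gl, c(1, 1, 1))
  H <- matrix(0L, 4, M)                      # all templates hom-ref
  post <- lsHmmPosterior(L, H, rep(0.01, M - 1), 0.01)$post
  expect_gt(post[2, 2], 0.99)
})

test_that("scaffold merging applies the window and masking rules", {
  mkcs <- function(pos, caller, ref = "A", alt = "G") {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1))
    callSet(gr, ref = rep(ref, length(pos)),
            alt = as.list(rep(alt, length(pos))),
            assays = list(GT = matrix(0L, length(pos), 2)),
            samples = c("a", "b"), caller = caller)
  }
  targets <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6, width = 1e4))
  seqcs <- mkcs(c(1e6 + 100, 1e6 + 500), "PBC")
  # empty scaffold: map is the sequence markers only
  m0 <- mergeScaffold(seqcs, NULL, targets)
  expect_equal(length(m0$gr), 2)
  expect_true(all(!m0$gr$masked))

  scaffold <- mkcs(c(1e6 - 400000,     # flanking, kept
                     1e6 - 600001,     # 600 kb away, excluded
                     1e6 + 200),       # inside the target, kept but masked
                   "CHIP")
  m1 <- mergeScaffold(seqcs, scaffold, targets)
  expect_equal(length(m1$gr), 4)
  expect_equal(sum(m1$gr$source == "scaffold"), 2)
  expect_equal(GenomicRanges::start(m1$gr)[m1$gr$masked], 1e6 + 200)
  # position-sorted
  expect_false(is.unsorted(GenomicRanges::start(m1$gr)))

  # allele mismatch at a shared position is an error
  clash <- mkcs(1e6 + 100, "CHIP", ref = "A", alt = "T")
  expect_error(mergeScaffold(seqcs, clash, targets), "mismatch")
})

test_that("dosage R-squared matches its closed form and bounds", {
  expect_equal(estimateRsq(c(0, 0, 1, 1)), 2 / 3, tolerance = 1e-12)
  expect_equal(estimateRsq(rep(1, 5)), 0)      # no variance at fbar = 0.5
  expect_equal(estimateRsq(rep(0, 5)), 0)      # fbar = 0 -> 0
  expect_equal(estimateRsq(rep(2, 5)), 0)      # fbar = 1 -> 0
  # hard HWE dosages approach 1
  set.seed(2)
  d <- rbinom(4000, 2, 0.3)
  expect_gt(estimateRsq(d), 0.95)
  expect_error(estimateRsq(1), "2 samples")
})

test_that("refinement is deterministic under a fixed seed", {
  cfg <- simConfig(n_samples = 25, n_target_sites = 60, n_flank_markers = 10,
                   seed = 15)
  sim <- simulateCohort(cfg)
  pbc <- callPBC(sim$pileup)
  hc <- hmmConfig(n_iterations = 4, burn_in = 1, n_reference_haplotypes = 8)
  set.seed(99)
  a <- refineLD(pbc, sim$scaffold, sim$targets, hc)
  set.seed(99)
  b <- refineLD(pbc, sim$scaffold, sim$targets, hc)
  expect_identical(assay(a, "PRA"), assay(b, "PRA"))
  expect_identical(gtMatrix(a), gtMatrix(b))
})

test_that("a single-sample cohort passes through the single-marker posteriors", {
  cfg <- simConfig(n_samples = 2, n_target_sites = 30, n_flank_markers = 0,
                   n_replicate_pairs = 0, seed = 44)
  sim <- simulateCohort(cfg)
  pbc <- callPBC(sim$pileup, samples = sampleIds(sim$pileup)[1])
  ldc <- refineLD(pbc)
  expect_equal(nrow(ldc), nrow(pbc))
  trip <- rowSums(cbind(assay(ldc, "PRR")[, 1], assay(ldc, "PRA")[, 1],
                        assay(ldc, "PAA")[, 1]))
  expect_equal(trip, rep(1, nrow(ldc)), tolerance = 1e-9)
})

test_that("posterior triplets are normalised and dosage is their expectation", {
  cfg <- simConfig(n_samples = 25, n_target_sites = 60, n_flank_markers = 10,
                   seed = 16)
  sim <- simulateCohort(cfg)
  pbc <- callPBC(sim$pileup)
  set.seed(1)
  ldc <- refineLD(pbc, sim$scaffold, sim$targets,
                  hmmConfig(n_iterations = 5, burn_in = 2,
                            n_reference_haplotypes = 8))
  p0 <- assay(ldc, "PRR"); p1 <- assay(ldc, "PRA"); p2 <- assay(ldc, "PAA")
  expect_equal(max(abs(p0 + p1 + p2 - 1)), 0, tolerance = 1e-9)
  expect_equal(assay(ldc, "DS"), p1 + 2 * p2, tolerance = 1e-12)
  expect_true(all(assay(ldc, "DS") >= 0 & assay(ldc, "DS") <= 2))
})

test_that("a missing genotype in perfect LD is imputed from its partner", {
  # two perfectly correlated markers; one sample has no reads at marker 2
  set.seed(8)
  n <- 40
  hap1 <- rbinom(n, 1, 0.5)
  hap2 <- rbinom(n, 1, 0.5)
  gt <- hap1 + hap2
  hit <- 0
  for (seed in 1:12) {
    set.seed(seed)
    gl_for <- function(d, depth = 12) {
      b <- c(rep("A", (2 - d) * depth / 2), rep("G", d * depth / 2))
      exp(genotypeLikelihoods(b, rep(30, length(b)))$loglik[c("AA", "AG", "GG")])
    }
    L1 <- t(vapply(gt, gl_for, numeric(3)))
    L2 <- L1
    L2[1, ] <- 1                       # sample 1: no data at marker 2
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1))
    cs <- callSet(gr, ref = c("A", "A"), alt = list("G", "G"),
                  assays = list(GT = matrix(NA_integer_, 2, n),
                                GQ = matrix(0, 2, n), DP = matrix(12L, 2, n),
                                LRR = rbind(log(L1[, 1]), log(L2[, 1])),
                                LRA = rbind(log(L1[, 2]), log(L2[, 2])),
                                LAA = rbind(log(L1[, 3]), log(L2[, 3]))),
                  samples = sprintf("s%02d", 1:n), caller = "PBC",
                  af = rep(mean(gt) / 2, 2))
    ldc <- refineLD(cs, cfg = hmmConfig(n_iterations = 6, burn_in = 2,
                                        n_reference_haplotypes = 12))
    imputed <- gtMatrix(ldc)[2, 1]
    want <- c(0L, 1L, 11L)[gt[1] + 1L]
    if (!is.na(imputed) && imputed == want) hit <- hit + 1
  }
  expect_gt(hit / 12, 0.75)
})
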