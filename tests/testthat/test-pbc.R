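test_that("the neutral-model polymorphism prior follows Watterson's formula", {
  expect_equal(polymorphismPrior(2), 0.001)
  expect_equal(polymorphismPrior(4), 0.001 * (1 + 1 / 2 + 1 / 3))
  # the full-cohort value (7,842 diploids)
  expect_equal(polymorphismPrior(15684), 0.001 * sum(1 / (1:15683)),
               tolerance = 1e-12)
  expect_lt(abs(polymorphismPrior(15684) - 0.010238), 1e-5)
  expect_error(polymorphismPrior(1), "chromosomes")
  # cap keeps it a proper prior
  expect_equal(polymorphismPrior(4, modelParams(theta = 0.4)), 0.5)
})

test_that("alternate-allele choice is quality-weighted with a fixed tie order", {
  expect_equal(chooseAlt(c(rep("G", 5), "T"), rep(20, 6), "A"), "G")
  expect_equal(chooseAlt(c(rep("G", 3), rep("T", 3)), rep(20, 6), "A"), "G")
  expect_equal(chooseAlt(c("A", "A", "T"), c(20, 20, 20), "A"), "T")
  expect_true(is.na(chooseAlt(c("A", "A"), c(20, 20), "A")))
  # one high-quality read outweighs several capped Q0 reads (weight 0.25)
  expect_equal(chooseAlt(c("G", "T", "T", "T"), c(40, 0, 0, 0), "A"), "G")
})

test_that("EM frequency estimation handles degenerate and boundary cases", {
  # point-mass likelihoods: one AA, one RR, one RA -> 3 alt alleles of 6
  trip <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  expect_equal(estimateFreqEM(trip), 0.5, tolerance = 1e-6)
  # no alternate evidence: floored at 1/(2n)
  trip2 <- matrix(rep(c(1, 1e-9, 1e-12), each = 5), 5)
  expect_equal(estimateFreqEM(trip2), 1 / 10, tolerance = 1e-4)
  expect_error(estimateFreqEM(matrix(numeric(0), 0, 3)), "empty")
})

test_that("EM frequency matches a fine grid search on random cohorts", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    # random well-behaved likelihood triplets
    trip <- matrix(runif(3 * n, min = 1e-3), n, 3)
    f_em <- estimateFreqEM(trip, tol = 1e-9, max_iter = 2000)
    grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
    loglik <- vapply(grid, function(f)
      sum(log(trip[, 1] * (1 - f)^2 + trip[, 2] * 2 * f * (1 - f) +
              trip[, 3] * f^2)), 0)
    f_grid <- grid[which.max(loglik)]
    f_grid <- max(f_grid, 1 / (2 * n))  # EM floors at one observable allele
    expect_lt(abs(f_em - f_grid), 1e-4 + 1e-8)
  }
})

test_that("polymorphism posterior behaves at its fixed points", {
  params <- modelParams()
  prior <- polymorphismPrior(20, params)
  # identical cohort likelihoods under both hypotheses -> posterior = prior
  trip <- matrix(rep(c(1, 1, 1), each = 4), 4)
  vp <- variantPosterior(trip, 1e-9, prior, params)
  expect_equal(vp$posterior, prior, tolerance = 1e-6)
  # strong hom-ref evidence -> posterior below the prior
  trip_ref <- matrix(rep(c(1, 1e-6, 1e-12), each = 10), 10, 3, byrow = FALSE)
  trip_ref <- matrix(c(rep(1, 10), rep(1e-6, 10), rep(1e-12, 10)), 10)
  vp2 <- variantPosterior(trip_ref, 0.05, prior, params)
  expect_lt(vp2$posterior, prior)
  # one clean het carrier among hom-ref samples -> confident variant
  gl_het <- exp(genotypeLikelihoods(c(rep("A", 5), rep("G", 5)),
                                    rep(20, 10))$loglik[c("AA", "AG", "GG")])
  gl_ref <- exp(genotypeLikelihoods(rep("A", 10),
                                    rep(20, 10))$loglik[c("AA", "AG", "GG")])
  trip3 <- rbind(gl_het, matrix(rep(gl_ref, 9), 9, byrow = TRUE))
  f_hat <- estimateFreqEM(trip3)
  vp3 <- variantPosterior(trip3, f_hat, polymorphismPrior(20, params), params)
  expect_true(vp3$is_variant)
  expect_gt(vp3$site_qual, 20)
})

test_that("frequency-prior genotype calls show the documented threshold behaviour", {
  flat <- matrix(c(1, 1, 1), 1)
  # zero reads at f = 0.01: hom-ref prior (0.99)^2 < 0.99 -> missing
  c1 <- callGenotypesPbc(flat, 0.01)
  expect_true(is.na(c1$genotype[1]))
  # zero reads at f = 0.001: (0.999)^2 = 0.998 >= 0.99 -> hom-ref called
  c2 <- callGenotypesPbc(flat, 0.001)
  expect_equal(c2$genotype[1], 0L)
  # clean 20x alternate sample -> hom-alt across admissible frequencies
  # (each alt read halves the het:hom-alt likelihood ratio, so ~20 reads
  # overcome the het prior even at low frequency)
  gl_alt <- exp(genotypeLikelihoods(rep("G", 20),
                                    rep(20, 20))$loglik[c("AA", "AG", "GG")])
  for (f in c(0.01, 0.05, 0.5)) {
    c3 <- callGenotypesPbc(matrix(gl_alt, 1), f)
    expect_equal(c3$genotype[1], 2L)
  }
})

test_that("the singleton polymorphism posterior decays with cohort size", {
  # fixed singleton carrier read data, growing all-reference cohort
  params <- modelParams()
  gl_het <- exp(genotypeLikelihoods(c(rep("A", 3), rep("G", 3)),
                                    rep(20, 6))$loglik[c("AA", "AG", "GG")])
  gl_ref <- exp(genotypeLikelihoods(rep("A", 12),
                                    rep(20, 12))$loglik[c("AA", "AG", "GG")])
  post <- vapply(c(10, 50, 200), function(n) {
    trip <- rbind(gl_het, matrix(rep(gl_ref, n - 1), n - 1, byrow = TRUE))
    f_hat <- estimateFreqEM(trip)
    variantPosterior(trip, f_hat, polymorphismPrior(2 * n, params),
                     params)$posterior
  }, 0)
  expect_true(all(diff(post) < 0))
})

test_that("cohort calling recovers allele frequencies within binomial error", {
  cfg <- simConfig(n_samples = 80, n_target_sites = 150, n_flank_markers = 0,
                   n_replicate_pairs = 0,
                   extra_count_sites = c(8L, 40L, 80L), seed = 5150)
  sim <- simulateCohort(cfg)
  pbc <- callPBC(sim$pileup)
  k <- paste0("chr1:", start(rowRanges(pbc)))
  tk <- paste0("chr1:", start(rowRanges(sim$truth)))
  m <- match(k, tk)
  af_true <- S4Vectors::mcols(rowRanges(sim$truth))$af[m]
  af_hat <- alleleFreq(pbc)
  keep <- af_true > 0
  se <- sqrt(pmax(af_true, 1 / 160) * (1 - pmax(af_true, 1 / 160)) / 160)
  expect_gt(mean(abs(af_hat - af_true)[keep] < 3 * se[keep] + 0.01), 0.95)
})

test_that("PBC misses fewer genotypes than IBC under the standard filters", {
  cfg <- simConfig(n_samples = 60, n_target_sites = 200, n_flank_markers = 0,
                   n_replicate_pairs = 0, seed = 77)
  sim <- simulateCohort(cfg)
  ibc <- applyGenotypeFilters(callIBC(sim$pileup))
  pbc <- applyGenotypeFilters(callPBC(sim$pileup))
  expect_lt(missingness(pbc), missingness(ibc))
})

test_that("replicate-aware subsetting restricts the called cohort", {
  cfg <- simConfig(n_samples = 30, n_target_sites = 60, n_flank_markers = 0,
                   n_replicate_pairs = 4, seed = 8)
  sim <- simulateCohort(cfg)
  pairs <- replicatePairs(sim$truth)
  run1 <- setdiff(sampleIds(sim$pileup), pairs$replicate)
  cs <- callPBC(sim$pileup, samples = run1)
  expect_setequal(colnames(cs), run1)
})
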