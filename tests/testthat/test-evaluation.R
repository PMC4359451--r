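# compact genotype-matrix call set builder
.evalCs <- function(gt, pos = seq_len(nrow(gt)) * 10, ref = "A", alt = "G",
                    caller = "PBC", samples = NULL) {
  S <- nrow(gt)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(gt)))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1))
  callSet(gr, ref = rep_len(ref, S), alt = as.list(rep_len(alt, S)),
          assays = list(GT = gt, DP = matrix(10L, S, ncol(gt)),
                        GQ = matrix(99, S, ncol(gt))),
          samples = samples, caller = caller)
}

test_that("Ts/Tv counts transitions and transversions with the multi-allelic rule", {
  # A>G (ts), C>T (ts), A>C (tv) -> 2.0
  df <- data.frame(ref = c("A", "C", "A"), alt = c("G", "T", "C"))
  expect_equal(tstv(df)$tstv, 2)
  # zero transversions -> flagged undefined
  r <- tstv(data.frame(ref = "A", alt = "G"))
  expect_false(r$defined)
  expect_true(is.na(r$tstv))
  # strand complement leaves the ratio unchanged
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  df2 <- data.frame(ref = comp[df$ref], alt = comp[df$alt])
  expect_equal(tstv(df2)$tstv, tstv(df)$tstv)
  # a triallelic site contributes one pair per alternate allele
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, width = 1))
  cs <- callSet(gr, ref = "A", alt = list(c("G", "C")),
                assays = list(GT = matrix(1L, 1, 1)), samples = "s1",
                caller = "IBC")
  r2 <- tstv(cs)
  expect_equal(r2$transitions, 1)
  expect_equal(r2$transversions, 1)
})

test_that("heterozygote mismatch follows the printed definition and is symmetric", {
  # identical het sets -> 0
  gA <- matrix(c(1L, 1L), 1)
  expect_equal(hetMismatch(.evalCs(gA), .evalCs(gA))$h_e, 0)
  # A: {s1 het, s2 het}; B: {s1 het, s2 hom} -> 1/(2+1)
  gB <- matrix(c(1L, 0L), 1)
  r <- hetMismatch(.evalCs(gA), .evalCs(gB))
  expect_equal(r$h_e, 1 / 3)
  # A: {het, hom}; B: {hom, het} -> 2/2
  gC <- matrix(c(1L, 0L), 1)
  gD <- matrix(c(0L, 1L), 1)
  expect_equal(hetMismatch(.evalCs(gC), .evalCs(gD))$h_e, 1)
  # symmetry
  expect_equal(hetMismatch(.evalCs(gC), .evalCs(gD))$h_e,
               hetMismatch(.evalCs(gD), .evalCs(gC))$h_e)
  # cells missing in either set are excluded
  gE <- matrix(c(1L, NA), 1)
  expect_equal(hetMismatch(.evalCs(gE), .evalCs(gB))$h_e, 0)
  expect_error(hetMismatch(.evalCs(gA, pos = 10), .evalCs(gA, pos = 999)),
               "shared")
})

test_that("replicate concordance restricts to pairs with a heterozygote", {
  pairs <- data.frame(sample = "s1", replicate = "s2")
  # identical members -> 0
  g <- rbind(c(1L, 1L), c(0L, 0L))
  expect_equal(replicateConcordance(.evalCs(g), pairs)$h_e, 0)
  # (het, hom-ref) at one site, nothing else het -> 1/1
  g2 <- matrix(c(1L, 0L), 1)
  expect_equal(replicateConcordance(.evalCs(g2), pairs)$h_e, 1)
  # sites where both members are hom are excluded from the denominator
  g3 <- rbind(c(1L, 1L), c(0L, 0L), c(11L, 11L))
  r <- replicateConcordance(.evalCs(g3), pairs)
  expect_equal(r$n_mismatch, 0L)
  expect_equal(r$h_e, 0)
  expect_error(replicateConcordance(.evalCs(g3), data.frame(
    sample = "s1", replicate = "zz")), "missing")
})

test_that("the additional-heterozygote audit isolates rescue genotypes", {
  truth <- .evalCs(rbind(c(1L, 0L), c(1L, 11L)))
  simple <- .evalCs(rbind(c(NA, 0L), c(NA, 11L)))
  complexx <- .evalCs(rbind(c(1L, 0L), c(1L, 11L)))
  # complex == simple -> nothing to audit
  r0 <- additionalHetAudit(simple, simple, truth)
  expect_equal(r0$n_extra_hets, 0L)
  # two extra hets, both matching truth hets -> h_e 0
  r1 <- additionalHetAudit(simple, complexx, truth)
  expect_equal(r1$n_extra_hets, 2L)
  expect_equal(r1$h_e, 0)
  # an extra het that truth calls hom counts as mismatch
  truth2 <- .evalCs(rbind(c(0L, 0L), c(1L, 11L)))
  r2 <- additionalHetAudit(simple, complexx, truth2)
  expect_equal(r2$n_mismatch, 1L)
  expect_equal(r2$h_e, 1 / (2 + 1))
})

test_that("missingness is the plain fraction of missing cells", {
  g <- matrix(0L, 10, 20)
  expect_equal(missingness(.evalCs(g)), 0)
  g[1, 1] <- NA
  expect_equal(missingness(.evalCs(g)), 1 / 200)
})

test_that("singleton summary identifies caller-specific singletons and carriers", {
  gA <- rbind(c(1L, 0L, 0L),     # singleton, carrier s1
              c(1L, 1L, 0L),     # two hets: not a singleton
              c(0L, 0L, 1L))     # singleton, carrier s3
  gB <- rbind(c(1L, 0L, 0L),
              c(1L, 1L, 0L))
  csA <- .evalCs(gA, pos = c(10, 20, 30))
  csB <- .evalCs(gB, pos = c(10, 20))
  ss <- singletonSummary(csA, csB)
  expect_equal(ss$a_specific$n_specific, 1)
  expect_equal(ss$a_specific$n_specific_singletons, 1)
  expect_equal(ss$a_specific$specific_singleton_keys, "chr1:30")
  expect_equal(ss$b_specific$n_specific, 0)
  # identical call sets -> no specifics
  ss2 <- singletonSummary(csA, csA)
  expect_equal(ss2$a_specific$n_specific, 0)
})

test_that("the exact Fisher test reproduces printed and degenerate values", {
  # the capillary-validation table: 30/30 vs 38/41
  expect_equal(fisherExact2x2(matrix(c(30, 0, 38, 3), 2, byrow = TRUE)),
               0.258, tolerance = 0.002)
  expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisherExact2x2(matrix(c(1, 0, 0, 1), 2)), 1)
  expect_error(fisherExact2x2(matrix(0, 2, 2)), "zero")
  # agreement with the standard implementation on random tables
  set.seed(31)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 8), 2)
    if (sum(tab) == 0) next
    expect_equal(fisherExact2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("known-site overlap matches by position and allele", {
  g <- matrix(1L, 4, 2)
  cs <- .evalCs(g, pos = c(10, 20, 30, 40))
  expect_equal(siteListOverlap(cs, data.frame(chrom = character(0),
                                              pos = integer(0),
                                              alt = character(0))), 0)
  all_known <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40), alt = "G")
  expect_equal(siteListOverlap(cs, all_known), 1)
  expect_equal(siteListOverlap(cs, all_known[1:2, ]), 0.5)
  # wrong allele does not count
  wrong <- data.frame(chrom = "chr1", pos = 10, alt = "T")
  expect_equal(siteListOverlap(cs, wrong), 0)
})

test_that("down-sampling recovery is 1 at full size for self-comparison and deterministic", {
  cfg <- simConfig(n_samples = 50, n_target_sites = 150, n_flank_markers = 0,
                   n_replicate_pairs = 0, seed = 909)
  sim <- simulateCohort(cfg)
  ibc <- applyGenotypeFilters(callIBC(sim$pileup))
  ss <- singletonSummary(ibc, ibc)
  keys <- ss$a_specific$singleton_keys
  k <- paste0("chr1:", start(rowRanges(ibc)))
  gt <- gtMatrix(ibc)
  carr <- vapply(match(keys, k), function(r) {
    j <- which(!is.na(gt[r, ]) & gtIsHet(gt[r, ]))
    colnames(ibc)[j[1]]
  }, "")
  expect_gt(length(keys), 3)
  set.seed(77)
  ds1 <- downsamplingExperiment(sim$pileup, keys, carr, sizes = c(20, 50))
  set.seed(77)
  ds2 <- downsamplingExperiment(sim$pileup, keys, carr, sizes = c(20, 50))
  expect_identical(ds1, ds2)                  # fixed seed -> fixed subsets
  expect_true(all(ds1$recovered >= 0 & ds1$recovered <= 1))
  expect_error(downsamplingExperiment(sim$pileup, keys, carr, sizes = 999),
               "exceeds")
})
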