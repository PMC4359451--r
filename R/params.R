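#' Calling model parameters
#'
#' Parameters shared by the individual- and population-based callers.
#'
#' @param theta Per-base-pair heterozygosity used in the reference-mismatch
#'   prior of the individual-based caller and in the neutral-model
#'   polymorphism prior of the population-based caller. Default 0.001.
#' @param posterior_threshold Minimum posterior probability for a genotype
#'   to be called rather than marked missing. Default 0.99.
#' @param error_floor_cap Upper bound on the per-base error probability
#'   derived from a PHRED score, so a Q0 base never carries probability 1 of
#'   being wrong. Default 0.75.
#' @param emit_threshold Minimum PHRED-scaled site quality for the
#'   population-based caller to emit a site as variant. Default 3
#'   (posterior probability of polymorphism > 0.5); the real selection is
#'   done downstream by site ranking.
#' @param prior_cap Upper cap on the neutral-model polymorphism prior.
#'   Default 0.5.
#' @return A validated list of class `ModelParams`.
#' @examples
#' p <- modelParams()
#' p$theta
#' @export
modelParams <- function(theta = 0.001, posterior_threshold = 0.99,
                        error_floor_cap = 0.75, emit_threshold = 3,
                        prior_cap = 0.5) {
  stopifnot(theta > 0, theta < 1,
            posterior_threshold > 0.5, posterior_threshold < 1,
            error_floor_cap > 0, error_floor_cap <= 1,
            emit_threshold >= 0, prior_cap > 0, prior_cap < 1)
  structure(list(theta = theta, posterior_threshold = posterior_threshold,
                 error_floor_cap = error_floor_cap,
                 emit_threshold = emit_threshold, prior_cap = prior_cap),
            class = "ModelParams")
}

#' Haplotype-copying HMM configuration
#'
#' Settings for the LD-aware genotype refiner.
#'
#' @param n_iterations Number of stochastic-EM iterations (default 30).
#' @param n_reference_haplotypes Number of template haplotypes `K` sampled
#'   (without replacement, from the other samples) for each individual at
#'   each iteration (default 200; capped at the available pool).
#' @param burn_in Iterations discarded before posterior averaging
#'   (default 10; must be smaller than `n_iterations`).
#' @param error_rate Initial per-allele copying error, re-estimated each
#'   iteration (default 0.01).
#' @param crossover_rate Initial per-marker-interval template switch
#'   probability, re-estimated each iteration (default 0.01).
#' @param chip_error Assumed genotyping error of scaffold (chip) genotypes
#'   used in their emission model (default 0.002).
#' @param flank_window Distance in bp around each target interval within
#'   which scaffold markers are used (default 500000).
#' @return A validated list of class `HmmConfig`.
#' @export
hmmConfig <- function(n_iterations = 30L, n_reference_haplotypes = 200L,
                      burn_in = 10L, error_rate = 0.01, crossover_rate = 0.01,
                      chip_error = 0.002, flank_window = 500000L) {
  n_iterations <- as.integer(n_iterations)
  n_reference_haplotypes <- as.integer(n_reference_haplotypes)
  burn_in <- as.integer(burn_in)
  stopifnot(n_iterations >= 1, burn_in >= 0, burn_in < n_iterations,
            n_reference_haplotypes >= 1,
            error_rate > 0, error_rate < 0.5,
            crossover_rate > 0, crossover_rate < 0.5,
            chip_error >= 0, chip_error < 0.5, flank_window >= 0)
  structure(list(n_iterations = n_iterations,
                 n_reference_haplotypes = n_reference_haplotypes,
                 burn_in = burn_in, error_rate = error_rate,
                 crossover_rate = crossover_rate, chip_error = chip_error,
                 flank_window = as.integer(flank_window)),
            class = "HmmConfig")
}

#' Synthetic cohort configuration
#'
#' Study conditions for the synthetic-data generator: a targeted (capture)
#' sequencing cohort with heterogeneous depth, founder-mosaic linkage
#' disequilibrium, a rare-variant-heavy site frequency spectrum, replicate
#' sample pairs and a chip-genotype scaffold.
#'
#' @param n_samples Number of unique individuals.
#' @param n_target_sites Number of candidate variant sites inside the target
#'   intervals.
#' @param n_flank_markers Number of common scaffold markers placed in the
#'   flanking windows around the targets.
#' @param n_genes Number of target intervals ("genes").
#' @param gene_span Width of each target interval in bp.
#' @param flank_window Flanking window in bp on each side of a target within
#'   which scaffold markers are placed (default 500 kb).
#' @param founders Number of founder haplotypes carrying the common-variant
#'   LD structure (default 12). Chosen so a desk-scale reference panel can
#'   cover the background haplotype diversity, mirroring the study setting
#'   where the 200-haplotype panel comfortably covered the local diversity
#'   of the target regions.
#' @param switch_rate Per-bp probability that a sample haplotype switches
#'   founder template between adjacent markers.
#' @param mean_depth Mean per-site per-sample read depth (default 24).
#' @param sample_disp_shape,site_disp_shape Gamma shape parameters of the
#'   unit-mean per-sample and per-site depth factors; smaller shapes give
#'   wider depth heterogeneity (defaults 20 and 2.5 span roughly 0 to >3x
#'   the mean per cell).
#' @param qual_values,qual_probs Discrete distribution of per-base PHRED
#'   qualities.
#' @param chip_error Per-genotype error rate of the simulated chip
#'   (default 0.002).
#' @param n_replicate_pairs Number of individuals sequenced twice; defaults
#'   to about 1% of the cohort (minimum 2), mirroring 80 pairs in 7,842.
#' @param ts_bias Probability that a simulated mutation is a transition
#'   (default 2/3, so the true Ts/Tv is about 2).
#' @param sfs_xi Exponent of the generalised site frequency spectrum
#'   P(count = i) proportional to i^(-xi). The stationary neutral model is
#'   xi = 1; the default 1.8 adds the rare-variant excess (about half of
#'   segregating sites are singletons) seen in large exonic cohorts.
#' @param common_threshold Minimum allele frequency for a variant to ride on
#'   the founder haplotypes (and be eligible for the chip scaffold).
#' @param known_freq Minimum true frequency for a variant to enter the
#'   emulated known-site (dbSNP-like) list.
#' @param artifact_fraction Fraction (of `n_target_sites`) of injected
#'   artifact sites showing heterozygote-excess noise, for ranking tests.
#' @param extra_count_sites Optional integer vector of alternate-allele
#'   counts; one additional site with exactly that true count is created per
#'   entry (useful for frequency-recovery experiments).
#' @param seed Mandatory integer seed; the generator is fully reproducible.
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(n_samples, n_target_sites = 1000L,
                      n_flank_markers = 60L, n_genes = 4L,
                      gene_span = 20000L, flank_window = 500000L,
                      founders = 12L, switch_rate = 2e-7,
                      mean_depth = 24, sample_disp_shape = 20,
                      site_disp_shape = 2.5,
                      qual_values = c(20L, 25L, 30L, 35L, 40L),
                      qual_probs = c(0.05, 0.15, 0.35, 0.30, 0.15),
                      chip_error = 0.002, n_replicate_pairs = NULL,
                      ts_bias = 2 / 3, sfs_xi = 1.8,
                      common_threshold = 0.05, known_freq = 0.01,
                      artifact_fraction = 0, extra_count_sites = integer(),
                      seed) {
  if (missing(seed)) stop("simConfig() requires an explicit seed")
  if (is.null(n_replicate_pairs))
    n_replicate_pairs <- max(2L, round(n_samples / 100))
  stopifnot(n_samples >= 2, n_target_sites >= 1, n_genes >= 1,
            founders >= 2, switch_rate >= 0, mean_depth > 0,
            sample_disp_shape > 0, site_disp_shape > 0,
            length(qual_values) == length(qual_probs),
            all(qual_values >= 0), all(qual_probs >= 0),
            chip_error >= 0, chip_error < 1,
            n_replicate_pairs >= 0, n_replicate_pairs <= n_samples,
            ts_bias >= 0, ts_bias <= 1, sfs_xi > 0,
            common_threshold > 0, common_threshold < 0.5,
            artifact_fraction >= 0, artifact_fraction < 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_target_sites = as.integer(n_target_sites),
                 n_flank_markers = as.integer(n_flank_markers),
                 n_genes = as.integer(n_genes),
                 gene_span = as.integer(gene_span),
                 flank_window = as.integer(flank_window),
                 founders = as.integer(founders),
                 switch_rate = switch_rate, mean_depth = mean_depth,
                 sample_disp_shape = sample_disp_shape,
                 site_disp_shape = site_disp_shape,
                 qual_values = as.integer(qual_values),
                 qual_probs = qual_probs / sum(qual_probs),
                 chip_error = chip_error,
                 n_replicate_pairs = as.integer(n_replicate_pairs),
                 ts_bias = ts_bias, sfs_xi = sfs_xi,
                 common_threshold = common_threshold,
                 known_freq = known_freq,
                 artifact_fraction = artifact_fraction,
                 extra_count_sites = as.integer(extra_count_sites),
                 seed = as.integer(seed)),
            class = "SimConfig")
}
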