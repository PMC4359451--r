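# capturecall

Likelihood-based single-nucleotide variant calling for targeted
(capture) sequencing with heterogeneous coverage, implementing three
classical calling strategies side by side so their trade-offs can be
measured on seed-reproducible synthetic cohorts with known truth:

* **IBC — individual-based single-marker calling.** Per sample and per
  site, the ten diploid genotype likelihoods
  `Pr(reads | g) = prod_j [ P(b_j|a_1)/2 + P(b_j|a_2)/2 ]` (with
  `P(b|a) = 1−e` on match and `e/3` otherwise, `e = 10^(−Q/10)`) are
  combined with a reference-mismatch prior (per-allele mismatch rate
  `θ = 0.001`, transitions and transversions exchangeable). A genotype
  is called when its posterior reaches 99%, and the union of all
  carriers defines the call set; multi-allelic sites arise naturally.
* **PBC — population-based calling.** The probability that a site is
  polymorphic is assessed against the stationary neutral-model prior
  `θ · Σ_{i<2n} 1/i` (Watterson), the population alternate-allele
  frequency `f` is estimated by EM under Hardy–Weinberg proportions
  `{(1−f)², 2f(1−f), f²}`, and genotypes are called with the frequency
  prior at the same 99% threshold.
* **LDC — LD-aware refinement.** A Li–Stephens haplotype-copying hidden
  Markov model (exact forward–backward over ordered template pairs,
  stochastic-EM rephasing, self-calibrated switch and copying-error
  rates) re-estimates every genotype from reads *and* haplotype
  context, optionally extended with chip genotypes at flanking markers
  within 500 kb of the targets; it reports dosages and per-site
  imputation quality `R²`.

Around the callers the package provides the matching QC ladder
(genotype filters GQ < 20 / depth < 7x / posterior ratio < 99:1, an
`R² < 0.7` site filter, SVM-based site ranking at a fixed call-set
size), the standard evaluation statistics (Ts/Tv, heterozygote mismatch
rate `h_e`, replicate concordance, missingness, singleton and
down-sampling analyses, exact Fisher test, known-site overlap), a fully
seeded synthetic cohort generator with truth tracking, and text I/O for
the mpileup dialect, VCF v4.2 and BED.

The intended audience is method developers and analysts of targeted /
exome sequencing studies who need to decide which calling strategy (or
combination) suits a cohort whose coverage is high on average but very
uneven per site and sample.

## Worked example

```r
library(capturecall)

cfg <- simConfig(n_samples = 150, n_target_sites = 400,
                 n_flank_markers = 40, seed = 7)
sim <- simulateCohort(cfg)
sim$pileup
#> CohortPileup: 400 sites x 152 samples
#>   mean depth: 23.94  depth range: 0-184

ibc <- applyGenotypeFilters(callIBC(sim$pileup))
pbc <- applyGenotypeFilters(callPBC(sim$pileup))
ldc <- applyGenotypeFilters(refineLD(callPBC(sim$pileup), sim$scaffold,
                                     sim$targets,
                                     hmmConfig(n_iterations = 12,
                                               burn_in = 8,
                                               n_reference_haplotypes = 24)))

round(100 * c(IBC = missingness(ibc), PBC = missingness(pbc),
              LDC = missingness(ldc)), 2)
#>  IBC  PBC  LDC
#> 7.54 0.69 0.64

round(100 * c(IBC = hetMismatch(ibc, sim$scaffold)$h_e,
              PBC = hetMismatch(pbc, sim$scaffold)$h_e,
              LDC = hetMismatch(ldc, sim$scaffold)$h_e), 2)
#>  IBC  PBC  LDC
#> 0.45 0.33 0.33
```

The three percentages in each block are the fraction of missing
genotype cells and the heterozygote mismatch rate against the (masked)
on-target chip genotypes. They reproduce the qualitative story the
package exists to demonstrate: the individual-based caller leaves an
order of magnitude more missing genotypes and the least accurate
common-variant heterozygotes; the population-based caller fixes most of
that with its frequency prior; LD-aware refinement with flanking
haplotypes is the most complete and most accurate. (Absolute values
depend on cohort size — a 150-sample toy cohort is not a 7,842-sample
study; orderings, not magnitudes, are the reproducible object.)

A thin command-line wrapper over the same functions ships in
`inst/scripts/capturecall` (subcommands `simulate`, `call-ibc`,
`call-pbc`, `filter`, `compare`).

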