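# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk.

# Pileup for explicit per-cell reads: `cells` is a list (one element per
# site) of lists (one element per sample) of list(bases=, quals=).
makePileup <- function(cells, ref, pos = seq_along(ref), chrom = "chr1",
                       samples = NULL) {
  S <- length(cells)
  N <- length(cells[[1]])
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(N))
  bases <- matrix("", S, N)
  quals <- matrix("", S, N)
  for (s in seq_len(S)) for (j in seq_len(N)) {
    b <- cells[[s]][[j]]$bases
    q <- cells[[s]][[j]]$quals
    bases[s, j] <- paste(b, collapse = "")
    quals[s, j] <- intToUtf8(q + 33L, multiple = FALSE)
  }
  cohortPileup(chrom, pos, ref, samples, bases, quals)
}

cellReads <- function(bases, quals) {
  if (length(quals) == 1) quals <- rep(quals, length(bases))
  list(bases = bases, quals = quals)
}

noReads <- function() list(bases = character(0), quals = integer(0))

# Reference R implementation of the genotype likelihood (naive product,
# no log space) used as an oracle against the compiled kernel.
naiveGenotypeLik <- function(bases, quals, cap = 0.75) {
  gn <- genotypeNames()
  lik <- sapply(gn, function(g) {
    p <- 1
    for (r in seq_along(bases)) {
      e <- min(10^(-quals[r] / 10), cap)
      al <- strsplit(g, "")[[1]]
      pb <- function(a) if (bases[r] == a) 1 - e else e / 3
      p <- p * (0.5 * pb(al[1]) + 0.5 * pb(al[2]))
    }
    p
  })
  lik
}

# Brute-force genotype-marginal oracle for the haplotype-copying HMM:
# enumerates all (K^2)^M state paths.
enumLsHmm <- function(L, H, rho, eps) {
  K <- nrow(H)
  M <- nrow(L)
  if (length(rho) == 1) rho <- rep(rho, max(M - 1, 0))
  copyp <- function(t1, t2) {
    p1 <- if (t1 == 1) 1 - eps else eps
    p2 <- if (t2 == 1) 1 - eps else eps
    c((1 - p1) * (1 - p2), p1 * (1 - p2) + (1 - p1) * p2, p1 * p2)
  }
  states <- expand.grid(j = seq_len(K), k = seq_len(K))
  ns <- nrow(states)
  trans <- function(a, b, r) ((1 - r) * (a == b) + r / K)
  paths <- as.matrix(expand.grid(rep(list(seq_len(ns)), M)))
  post <- matrix(0, M, 3)
  tot <- 0
  for (p in seq_len(nrow(paths))) {
    w <- 1 / ns
    emis <- numeric(M)
    for (m in seq_len(M)) {
      st <- paths[p, m]
      cp <- copyp(H[states$j[st], m], H[states$k[st], m])
      emis[m] <- sum(cp * L[m, ])
      w <- w * emis[m]
      if (m > 1) {
        s0 <- paths[p, m - 1]
        w <- w * trans(states$j[s0], states$j[st], rho[m - 1]) *
          trans(states$k[s0], states$k[st], rho[m - 1])
      }
    }
    if (w == 0) next
    tot <- tot + w
    for (m in seq_len(M)) {
      st <- paths[p, m]
      cp <- copyp(H[states$j[st], m], H[states$k[st], m])
      post[m, ] <- post[m, ] + w * cp * L[m, ] / emis[m]
    }
  }
  post / tot
}

# small deterministic truth-vs-callset genotype concordance
truthConcordance <- function(cs, truth, min_af = 0) {
  tk <- paste0(as.character(GenomicRanges::seqnames(rowRanges(truth))), ":",
               GenomicRanges::start(rowRanges(truth)))
  k <- paste0(as.character(GenomicRanges::seqnames(rowRanges(cs))), ":",
              GenomicRanges::start(rowRanges(cs)))
  m <- match(k, tk)
  ok <- !is.na(m) & S4Vectors::mcols(rowRanges(truth))$af[m] >= min_af
  g <- gtMatrix(cs)[ok, colnames(cs), drop = FALSE]
  t2 <- truthGenotypes(truth)[m[ok], colnames(cs), drop = FALSE]
  mean(g == t2, na.rm = TRUE)
}
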