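#' Read an mpileup-style text file
#'
#' Parses the common subset of the samtools mpileup text dialect: one line
#' per position with `chrom pos ref` followed by `depth bases quals` for
#' each sample of a declared roster. In the base string, `.` and `,` mean
#' a reference match, `ACGTacgt` are explicit bases, `^X` (read start plus
#' mapping quality) and `$` (read end) are stripped, and indel tokens
#' (`+NXXX`/`-NXXX`) and deletion placeholders (`*`) are skipped with a
#' warning counter. Qualities are PHRED+33.
#'
#' @param path File path.
#' @param samples Sample identifiers, in column order.
#' @return A [CohortPileup]; `metadata` attribute `skipped_tokens` counts
#'   the indel/deletion tokens that were dropped.
#' @export
readPileup <- function(path, samples) {
  lines <- readLines(path)
  n <- length(samples)
  S <- length(lines)
  chrom <- character(S)
  pos <- integer(S)
  ref <- character(S)
  bases <- matrix("", S, n)
  quals <- matrix("", S, n)
  skipped <- 0L
  for (li in seq_len(S)) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3 + 3 * n)
      stop("line ", li, ": expected ", 3 + 3 * n, " fields, got ", length(f))
    chrom[li] <- f[1]
    pos[li] <- as.integer(f[2])
    if (is.na(pos[li]) || pos[li] < 1) stop("line ", li, ": bad position")
    ref[li] <- toupper(f[3])
    if (!ref[li] %in% .ALLELES) stop("line ", li, ": bad reference base")
    for (j in seq_len(n)) {
      depth <- as.integer(f[3 * j + 1])
      braw <- f[3 * j + 2]
      qraw <- f[3 * j + 3]
      if (identical(braw, "*") && depth == 0) braw <- ""
      if (identical(qraw, "*") && depth == 0) qraw <- ""
      p <- .parseBaseString(braw, ref[li])
      skipped <- skipped + p$skipped
      if (nchar(p$bases) != nchar(qraw))
        stop("line ", li, ", sample ", samples[j],
             ": base/quality length mismatch")
      if (nchar(p$bases) != depth)
        stop("line ", li, ", sample ", samples[j],
             ": declared depth disagrees with base string")
      bases[li, j] <- p$bases
      quals[li, j] <- qraw
    }
  }
  out <- cohortPileup(chrom, pos, ref, samples, bases, quals)
  attr(out, "skipped_tokens") <- skipped
  out
}

## resolve one mpileup base string to explicit upper-case bases
.parseBaseString <- function(s, ref) {
  out <- character(0)
  chars <- strsplit(s, "")[[1]]
  i <- 1L
  skipped <- 0L
  while (i <= length(chars)) {
    c <- chars[i]
    if (c == "^") { i <- i + 2L; next }            # read start + mapq char
    if (c == "$") { i <- i + 1L; next }            # read end
    if (c %in% c("+", "-")) {                      # indel token
      j <- i + 1L
      while (j <= length(chars) && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1):(j - 1)], collapse = ""))
      i <- j + len
      skipped <- skipped + 1L
      next
    }
    if (c == "*") { skipped <- skipped + 1L; i <- i + 1L; next }
    if (c %in% c(".", ",")) out <- c(out, ref)
    else if (toupper(c) %in% .ALLELES) out <- c(out, toupper(c))
    else stop("unsupported pileup token '", c, "'")
    i <- i + 1L
  }
  list(bases = paste(out, collapse = ""), skipped = skipped)
}

#' Write a pileup as mpileup-style text
#'
#' Inverse of [readPileup()]: reference-matching reads are written as `.`,
#' other bases explicitly; qualities as PHRED+33. A zero-depth cell is
#' written `0 * *`.
#'
#' @param pileup A [CohortPileup].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePileup <- function(pileup, path) {
  gr <- rowRanges(pileup)
  ref <- refAllele(pileup)
  bm <- pileupBases(pileup)
  qm <- pileupQuals(pileup)
  S <- nrow(bm)
  cols <- character(ncol(bm))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seq_len(S)) {
    row <- vapply(seq_len(ncol(bm)), function(j) {
      b <- bm[s, j]
      d <- nchar(b)
      if (d == 0) return("0\t*\t*")
      bb <- strsplit(b, "")[[1]]
      bb[bb == ref[s]] <- "."
      paste0(d, "\t", paste(bb, collapse = ""), "\t", qm[s, j])
    }, "")
    writeLines(paste(c(as.character(seqnames(gr))[s], start(gr)[s], ref[s],
                       row), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a call set as VCF v4.2
#'
#' Emits `CHROM POS ID REF ALT QUAL FILTER INFO FORMAT` plus one genotype
#' column per sample. INFO carries `NS`, `AF` and (when present) `R2`;
#' FORMAT carries `GT`, and whichever of `GQ` (rounded), `DP` and `DS`
#' (4 decimals) the call set holds. Missing genotypes are `./.`.
#'
#' @param callset A [CallSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeVcf <- function(callset, path) {
  gr <- rowRanges(callset)
  alt <- vapply(altAlleles(callset), paste, "", collapse = ",")
  have <- assayNames(callset)
  fmt <- c("GT", intersect(c("GQ", "DP", "DS"), have))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=capturecall",
           "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Number of samples\">",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
           if ("R2" %in% names(mcols(gr)))
             "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation R-squared\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           if ("GQ" %in% fmt)
             "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           if ("DP" %in% fmt)
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           if ("DS" %in% fmt)
             "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(callset)), collapse = "\t"))
  gt <- gtMatrix(callset)
  gtxt <- gtText(gt)
  pieces <- list(gtxt)
  if ("GQ" %in% fmt) {
    gq <- round(gqMatrix(callset))
    pieces <- c(pieces, list(ifelse(is.na(gq), ".", as.character(gq))))
  }
  if ("DP" %in% fmt) pieces <- c(pieces, list(as.character(dpMatrix(callset))))
  if ("DS" %in% fmt)
    pieces <- c(pieces, list(sprintf("%.4f", assay(callset, "DS"))))
  cells <- do.call(function(...) paste(..., sep = ":"), pieces)
  dim(cells) <- dim(gt)
  info <- paste0("NS=", ncol(callset), ";AF=",
                 signif(alleleFreq(callset), 6))
  if ("R2" %in% names(mcols(gr)))
    info <- paste0(info, ";R2=", sprintf("%.4f", mcols(gr)$R2))
  qual <- siteQual(callset)
  recs <- paste(as.character(seqnames(gr)), start(gr), ".",
                refAllele(callset), alt,
                ifelse(is.na(qual), ".", sprintf("%.2f", qual)),
                "PASS", info, paste(fmt, collapse = ":"),
                apply(cells, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a VCF into a CallSet
#'
#' Reads a VCF (via the vcfR parser) into a `"CHIP"`-style [CallSet]
#' keeping `GT` and, when present, `GQ`, `DP`, `DS` and the `AF`/`R2`
#' INFO fields. Intended for chip-scaffold panels and for round-tripping
#' this package's own output; genotypes with more than one ALT allele are
#' kept with their allele indexes.
#'
#' @param path VCF path.
#' @param caller Caller tag for the resulting [CallSet] (default
#'   `"CHIP"`).
#' @return A [CallSet].
#' @export
readVcf <- function(path, caller = "CHIP") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readVcf needs the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(v, "GT")
  parse_gt <- function(x) {
    a <- strsplit(x, "[/|]")
    i1 <- suppressWarnings(as.integer(vapply(a, `[`, "", 1)))
    i2 <- suppressWarnings(as.integer(vapply(a, function(z) z[min(2, length(z))], "")))
    out <- .gtCode(i1, i2)
    out[is.na(i1) | is.na(i2)] <- NA_integer_
    out
  }
  gt <- matrix(parse_gt(as.vector(gt_raw)), nrow(gt_raw), ncol(gt_raw))
  assays <- list(GT = gt)
  fmt_fields <- unique(unlist(strsplit(v@gt[, 1], ":")))
  if ("GQ" %in% fmt_fields)
    assays$GQ <- apply(vcfR::extract.gt(v, "GQ"), 2, as.numeric)
  if ("DP" %in% fmt_fields)
    assays$DP <- apply(vcfR::extract.gt(v, "DP"), 2, as.integer)
  if ("DS" %in% fmt_fields)
    assays$DS <- apply(vcfR::extract.gt(v, "DS"), 2, as.numeric)
  assays <- lapply(assays, function(a) {
    if (is.null(dim(a))) a <- matrix(a, nrow = nrow(gt))
    a
  })
  info_field <- function(key) {
    m <- regmatches(fix[, "INFO"],
                    regexpr(paste0("(^|;)", key, "=[^;]+"), fix[, "INFO"]))
    has <- grepl(paste0(key, "="), fix[, "INFO"])
    out <- rep(NA_real_, nrow(fix))
    out[has] <- as.numeric(sub(paste0(".*", key, "="), "", m))
    out
  }
  af <- info_field("AF")
  r2 <- info_field("R2")
  gr <- GRanges(fix[, "CHROM"], IRanges(as.integer(fix[, "POS"]), width = 1L))
  callSet(gr, ref = fix[, "REF"],
          alt = strsplit(fix[, "ALT"], ",", fixed = TRUE),
          assays = assays, samples = colnames(gt_raw), caller = caller,
          qual = suppressWarnings(as.numeric(fix[, "QUAL"])), af = af,
          rsq = if (!all(is.na(r2))) r2 else NULL)
}

#' Read target intervals from a BED file
#'
#' Uses the rtracklayer importer, which converts the 0-based half-open BED
#' coordinates to the 1-based closed `GRanges` convention used throughout
#' this package.
#'
#' @param path BED path.
#' @return `GRanges` of target intervals.
#' @export
readTargetsBed <- function(path) {
  rtracklayer::import(path, format = "BED")
}
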