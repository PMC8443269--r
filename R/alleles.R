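#' Read a SNP table (chrom, pos, ref allele, alt allele)
#'
#' Single-nucleotide substitutions distinguishing two haplotypes (e.g. the
#' M. musculus reference vs the M. spretus allele). Positions are 0-based.
#'
#' @param path TSV path with columns chrom, pos, ref, alt (no header, `#`
#'   comments allowed).
#' @param genome Optional `Seqinfo`.
#' @return A data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`.
#' @export
readSnpTable <- function(path, genome = NULL) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  snps <- data.frame(chrom = as.character(tab[[1]]),
                     pos = as.integer(tab[[2]]),
                     ref = toupper(as.character(tab[[3]])),
                     alt = toupper(as.character(tab[[4]])),
                     stringsAsFactors = FALSE)
  validateSnpTable(snps)
  snps
}

validateSnpTable <- function(snps) {
  if (any(nchar(snps$ref) != 1 | nchar(snps$alt) != 1))
    stop("alleles must be single bases")
  if (any(snps$ref == snps$alt)) stop("ref and alt alleles must differ")
  if (anyDuplicated(snps[c("chrom", "pos")]))
    stop("duplicate SNP positions")
  invisible(snps)
}

#' Substitute SNP alleles into a reference genome
#'
#' Produces the second haplotype's genome in silico by replacing every SNP
#' position in the reference with the alternate allele. Sequence lengths
#' are unchanged; the reference base at every SNP is checked first.
#'
#' @param refGenome A `DNAStringSet` (names = chromosomes).
#' @param snps A SNP table (see [readSnpTable()]).
#' @return A `DNAStringSet` identical to `refGenome` except at substituted
#'   positions.
#' @export
buildHybridGenome <- function(refGenome, snps) {
  validateSnpTable(snps)
  out <- refGenome
  for (c1 in unique(snps$chrom)) {
    if (!c1 %in% names(out)) stop("SNP chromosome not in genome: ", c1)
    rows <- snps[snps$chrom == c1, ]
    at <- rows$pos + 1L
    have <- as.character(Biostrings::extractAt(
      out[[c1]], IRanges::IRanges(at, width = 1L)))
    bad <- toupper(have) != rows$ref
    if (any(bad))
      stop("reference base mismatch at ", c1, ":",
           paste(utils::head(rows$pos[bad], 10), collapse = ","),
           " (found ", paste(utils::head(have[bad], 10), collapse = ","), ")")
    out[[c1]] <- Biostrings::replaceLetterAt(
      out[[c1]], at, paste(rows$alt, collapse = ""))
  }
  out
}

#' Assign reads to haplotypes via diagnostic SNPs and build allele depths
#'
#' A read is assigned to a haplotype iff it overlaps at least one SNP
#' position and has zero mismatches against that haplotype's genome; reads
#' overlapping no SNP, carrying residual mismatches against both genomes,
#' or (degenerately) matching both are dropped. Surviving reads are
#' accumulated into one coverage track per haplotype.
#'
#' @param reads data.frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `mmA`, `mmB` (mismatch counts against haplotype A and B
#'   genomes).
#' @param snps SNP table.
#' @param genome `Seqinfo` genome index.
#' @return A list of class `alleleDepths`: `hapA`, `hapB`
#'   ([SignalTrack-class]), `assigned` (factor "A"/"B"/"dropped" per read),
#'   `nA`, `nB`, `nDropped`.
#' @export
filterDiagnosticReads <- function(reads, snps, genome) {
  gr <- fragmentsGRanges(reads$chrom, reads$start, reads$end, genome)
  snpGr <- GenomicRanges::GRanges(snps$chrom,
    IRanges::IRanges(snps$pos + 1L, width = 1L))
  hasSnp <- IRanges::overlapsAny(gr, snpGr)
  isA <- hasSnp & reads$mmA == 0 & reads$mmB > 0
  isB <- hasSnp & reads$mmB == 0 & reads$mmA > 0
  assigned <- factor(ifelse(isA, "A", ifelse(isB, "B", "dropped")),
                     levels = c("A", "B", "dropped"))
  hapA <- coverageTrack(gr[isA])
  hapB <- coverageTrack(gr[isB])
  structure(list(hapA = hapA, hapB = hapB, assigned = assigned,
                 nA = sum(isA), nB = sum(isB),
                 nDropped = sum(assigned == "dropped")),
            class = "alleleDepths")
}

#' S/G1 replication profile as fraction of median
#'
#' Per-bin ratio of S-phase to G1-phase read depth (G1-zero bins dropped),
#' divided by the median ratio over the retained bins so the profile's
#' median is 1. Early-replicating loci sit above 1, late loci below.
#'
#' @param sDepth,g1Depth `SignalTrack`s from the same haplotype/genome.
#' @param binSize Bin size in bp.
#' @return `GRanges` of retained bins with `score`.
#' @export
sseqProfile <- function(sDepth, g1Depth, binSize) {
  sB <- binTrack(sDepth, binSize)
  gB <- binTrack(g1Depth, binSize)
  if (sum(gB$score) == 0) stop("G1 track is all zero")
  keep <- gB$score > 0
  out <- sB[keep]
  out$score <- sB$score[keep] / gB$score[keep]
  m <- stats::median(out$score)
  if (m == 0) stop("median S/G1 ratio is 0")
  out$score <- out$score / m
  out
}

# unscaled median absolute deviation from the median
.mad0 <- function(x) stats::median(abs(x - stats::median(x)))

#' Per-chromosome replication fluctuation statistic (MAD ratio)
#'
#' For each chromosome, the median absolute deviation (unscaled) of each
#' haplotype's S-phase profile measures the amplitude of its replication
#' timing fluctuations; their ratio A/B flags chromosomes whose two
#' homologs replicate differently. With one homolog heterochromatic and
#' late-replicating (the inactive X), its compressed timing signal drives
#' the ratio far from 1, making the X the outlier among chromosomes.
#'
#' @param profileA,profileB `GRanges` binned profiles (same chromosomes and
#'   binning), e.g. from [sseqProfile()].
#' @return A list of class `fluctuationStat`: `table` (data.frame chrom,
#'   madA, madB, ratio, flag) sorted by decreasing ratio, and `outlier`
#'   (chromosome with the maximal defined ratio).
#' @export
fluctuationRatio <- function(profileA, profileB) {
  chA <- as.character(GenomicRanges::seqnames(profileA))
  chB <- as.character(GenomicRanges::seqnames(profileB))
  chroms <- unique(chA)
  if (!setequal(chroms, unique(chB))) stop("chromosome sets differ")
  rows <- lapply(chroms, function(c1) {
    a <- profileA$score[chA == c1]
    b <- profileB$score[chB == c1]
    madA <- .mad0(a); madB <- .mad0(b)
    data.frame(chrom = c1, madA = madA, madB = madB,
               ratio = if (madB > 0) madA / madB else NA_real_,
               flag = if (madB > 0) NA_character_ else "undefined (MAD_B = 0)",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-ifelse(is.na(tab$ratio), -Inf, tab$ratio)), ]
  rownames(tab) <- NULL
  outlier <- if (any(!is.na(tab$ratio))) tab$chrom[which.max(tab$ratio)] else
    NA_character_
  structure(list(table = tab, outlier = outlier), class = "fluctuationStat")
}

#' Haplotype balance of MCM (ChEC) reads in a region
#'
#' Ratio of haplotype A to haplotype B summed read depth over a region,
#' with optional per-haplotype normalization by matching G1 control depths.
#' A ratio near 1 means both homologs are equally licensed.
#'
#' @param chec An `alleleDepths` from ChEC reads.
#' @param control Optional `alleleDepths` from sonicated G1 DNA.
#' @param chrom Chromosome of the region.
#' @param start0,end0 0-based half-open bounds; defaults cover the
#'   chromosome.
#' @return A list: `ratio` (A/B), `sumA`, `sumB`, `flag`.
#' @export
alleleMcmBalance <- function(chec, control = NULL, chrom,
                             start0 = 0L, end0 = NULL) {
  if (is.null(end0)) end0 <- length(trackValues(chec$hapA)[[chrom]])
  a <- sum(trackWindow(chec$hapA, chrom, start0, end0))
  b <- sum(trackWindow(chec$hapB, chrom, start0, end0))
  if (!is.null(control)) {
    ca <- sum(trackWindow(control$hapA, chrom, start0, end0))
    cb <- sum(trackWindow(control$hapB, chrom, start0, end0))
    if (ca == 0 || cb == 0)
      return(list(ratio = NA_real_, sumA = a, sumB = b,
                  flag = "control depth is zero"))
    a <- a / ca; b <- b / cb
  }
  if (b == 0)
    return(list(ratio = NA_real_, sumA = a, sumB = b,
                flag = "no haplotype-B signal in region"))
  list(ratio = a / b, sumA = a, sumB = b, flag = NA_character_)
}
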