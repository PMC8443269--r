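#' Bin a per-bp track into fixed-width bins
#'
#' Bins tile each chromosome left to right; each bin value is the sum of
#' per-bp depth within it, so the binned total equals the track mass
#' exactly. A trailing partial bin is kept and flagged.
#'
#' @param track A [SignalTrack-class].
#' @param binSize Bin width in bp (>= 1). 1 kb bins are used for the
#'   replication simulator and zone comparisons, 5 kb bins for the
#'   dispersion metrics.
#' @return A `GRanges` tiling the genome with columns `score` (bin sum) and
#'   `partial` (logical).
#' @export
binTrack <- function(track, binSize) {
  binSize <- as.integer(binSize)
  if (binSize < 1L) stop("binSize must be >= 1")
  vals <- trackValues(track)
  si <- genomeIndex(names(vals), lengths(vals))
  out <- lapply(names(vals), function(ch) {
    v <- vals[[ch]]
    L <- length(v)
    starts <- seq(1L, L, by = binSize)
    width <- pmin(binSize, L - starts + 1L)
    sums <- IRanges::viewSums(IRanges::Views(v, start = starts, width = width))
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts, width = width),
                           score = as.numeric(sums),
                           partial = width < binSize, seqinfo = si)
  })
  do.call(c, out)
}

#' Smooth a binned signal with a centered sliding window
#'
#' Centered moving average over `windowBins` bins per chromosome; at the
#' edges the window shrinks to the bins available. The 240 kb overview
#' traces use 1 kb bins smoothed with a 15-bin window.
#'
#' @param binned `GRanges` from [binTrack()].
#' @param windowBins Odd window size in bins.
#' @return The input `GRanges` with smoothed `score`.
#' @export
smoothBins <- function(binned, windowBins) {
  windowBins <- as.integer(windowBins)
  if (windowBins %% 2L != 1L) stop("windowBins must be odd")
  half <- windowBins %/% 2L
  ch <- as.character(GenomicRanges::seqnames(binned))
  sc <- binned$score
  for (c1 in unique(ch)) {
    idx <- which(ch == c1)
    x <- sc[idx]; n <- length(x)
    if (windowBins > n) stop("window larger than chromosome (in bins)")
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    sc[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  binned$score <- sc
  binned
}

#' Dispersion of a binned signal: top/bottom quantile ratio and cumulative curve
#'
#' How focused is MCM loading along the chromosome? The metric is the ratio
#' of the median bin value in the top `q` fraction of bins to that in the
#' bottom `q` fraction (q = 0.05 by default), plus the cumulative share of
#' total signal captured by bins sorted in descending order. Focused
#' landscapes (budding-yeast-like) give large ratios and capture 80% of the
#' signal in few bins; dispersed landscapes (fission-yeast/human-like) do
#' not.
#'
#' @param binned `GRanges` from [binTrack()] (or any `GRanges` with `score`).
#' @param q Tail fraction (default 0.05). `round(q*N)` bins, at least 1,
#'   are taken from each tail, ranked by value with ties broken by
#'   genomic position.
#' @return A list: `ratio`, `infinite` (logical flag when the bottom median
#'   is 0), `topMedian`, `bottomMedian`, and `curve` (data.frame with
#'   `binFraction`, `signalFraction`).
#' @export
dispersionReport <- function(binned, q = 0.05) {
  x <- binned$score
  n <- length(x)
  k <- max(1L, as.integer(round(q * n)))
  if (2L * k > n) stop("not enough bins for tail fraction q")
  ord <- order(-x, seq_along(x))       # descending, ties by coordinate
  top <- x[ord[seq_len(k)]]
  bottom <- x[ord[seq(n - k + 1L, n)]]
  tm <- stats::median(top); bm <- stats::median(bottom)
  inf <- bm == 0
  total <- sum(x)
  curve <- data.frame(
    binFraction = seq_len(n) / n,
    signalFraction = if (total > 0) cumsum(x[ord]) / total else rep(NA_real_, n))
  list(ratio = if (inf) Inf else tm / bm, infinite = inf,
       topMedian = tm, bottomMedian = bm, curve = curve)
}

#' Fraction of bins needed to reach a cumulative signal fraction
#'
#' @param report A [dispersionReport()] result.
#' @param signalFraction Target cumulative signal share (default 0.8).
#' @return The smallest bin fraction whose cumulative signal reaches the
#'   target.
#' @export
binsForSignalFraction <- function(report, signalFraction = 0.8) {
  cv <- report$curve
  i <- which(cv$signalFraction >= signalFraction)[1]
  if (is.na(i)) return(NA_real_)
  cv$binFraction[i]
}

#' Express a binned signal as fraction of the genome-wide median bin
#'
#' @param binned `GRanges` with `score`.
#' @return The input with `score` divided by the median bin value.
#' @export
fractionOfMedian <- function(binned) {
  m <- stats::median(binned$score)
  if (m == 0) stop("median bin value is 0")
  binned$score <- binned$score / m
  binned
}

#' Mean signal as a function of bin AT content
#'
#' Divides the genome into `binSize` bp bins (default 30) and reports the
#' mean binned signal over all bins with exactly k A/T bases, for
#' k = 0..`binSize`. Lowercase and uppercase bases count equally; bins
#' containing any non-ACGT base, and trailing partial bins, are ineligible.
#' Empty classes are reported as `NA`, not 0.
#'
#' @param genomeSeq A [Biostrings::DNAStringSet] (names = chromosomes).
#' @param track A `SignalTrack` over the same genome.
#' @param binSize AT-counting bin width (default 30).
#' @return data.frame with `atCount`, `meanSignal`, `nBins`.
#' @export
atContentProfile <- function(genomeSeq, track, binSize = 30L) {
  binSize <- as.integer(binSize)
  binned <- binTrack(track, binSize)
  atAll <- integer(0); sigAll <- numeric(0)
  for (ch in names(genomeSeq)) {
    seq <- genomeSeq[[ch]]
    L <- length(seq)
    nFull <- L %/% binSize
    if (nFull == 0) next
    v <- Biostrings::Views(seq, start = seq(1L, by = binSize, length.out = nFull),
                           width = binSize)
    at <- Biostrings::letterFrequency(v, letters = "AT")[, 1]
    acgt <- Biostrings::letterFrequency(v, letters = "ACGT")[, 1]
    eligible <- acgt == binSize
    idx <- which(as.character(GenomicRanges::seqnames(binned)) == ch &
                   !binned$partial)
    sig <- binned$score[idx][seq_len(nFull)]
    atAll <- c(atAll, at[eligible]); sigAll <- c(sigAll, sig[eligible])
  }
  res <- data.frame(atCount = 0:binSize, meanSignal = NA_real_, nBins = 0L)
  if (length(atAll)) {
    tab <- tapply(sigAll, factor(atAll, levels = 0:binSize), mean)
    cnt <- tapply(sigAll, factor(atAll, levels = 0:binSize), length)
    res$meanSignal <- as.numeric(tab)
    res$nBins <- ifelse(is.na(cnt), 0L, as.integer(cnt))
  }
  res
}

#' Pearson correlation between two identically binned signals
#'
#' @param a,b `GRanges` with `score`, identical binning.
#' @param exclude Optional `GRanges`; bins overlapping it are dropped.
#' @return A list: `r` (Pearson, `NA` with `flag` when either side has zero
#'   variance), `n` bins used, `flag`.
#' @export
trackCorrelation <- function(a, b, exclude = NULL) {
  if (length(a) != length(b)) stop("bin sets differ in length")
  keep <- rep(TRUE, length(a))
  if (!is.null(exclude))
    keep <- !IRanges::overlapsAny(a, exclude)
  x <- a$score[keep]; y <- b$score[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n = sum(keep), flag = "zero variance"))
  list(r = stats::cor(x, y), n = sum(keep), flag = NA_character_)
}

#' Per-origin paired scatter: values vs an external reference
#'
#' @param values Named numeric vector (names = origin identifiers).
#' @param reference Named numeric vector over the same origins.
#' @return A list: `table` (data.frame origin/value/reference) and `r`.
#' @export
originScatter <- function(values, reference) {
  if (!setequal(names(values), names(reference))) {
    onlyA <- setdiff(names(values), names(reference))
    onlyB <- setdiff(names(reference), names(values))
    stop("origin sets differ; only in values: ",
         paste(utils::head(onlyA, 5), collapse = ","),
         "; only in reference: ", paste(utils::head(onlyB, 5), collapse = ","))
  }
  reference <- reference[names(values)]
  tab <- data.frame(origin = names(values), value = as.numeric(values),
                    reference = as.numeric(reference))
  list(table = tab, r = stats::cor(tab$value, tab$reference))
}
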