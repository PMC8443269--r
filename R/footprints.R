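#' Footprint classifier configuration
#'
#' Parameters for the single-vs-multiple MCM double-hexamer classifier.
#' A licensed origin carrying exactly one double hexamer concentrates its
#' short-fragment (51-100 bp) ChEC signal within ~60 bp of the signal peak;
#' origins licensed at several sub-sites spread it further.
#'
#' @param peakHalfwidth bp on each side of the peak counted as the single
#'   footprint (default 60).
#' @param flank bp beyond the annotated origin boundaries included in the
#'   classification window (default 800).
#' @param noiseFrac Per-bp depths below this fraction of the peak height are
#'   treated as noise and excluded (default 0.10).
#' @param singleThreshold Minimum single-footprint fraction for the
#'   "single" class, inclusive (default 0.80).
#' @param sizeClass Fragment size class for classification (default 51-100).
#' @param abundanceFlank bp on each side of the origin center summed for
#'   abundance (default 800).
#' @param noiseCutDenominatorOnly Apply the noise cutoff to the denominator
#'   only (default `FALSE`: applied per-bp to both sums).
#' @return A list of class `classifierConfig`.
#' @export
classifierConfig <- function(peakHalfwidth = 60L, flank = 800L,
                             noiseFrac = 0.10, singleThreshold = 0.80,
                             sizeClass = c(51L, 100L), abundanceFlank = 800L,
                             noiseCutDenominatorOnly = FALSE) {
  stopifnot(noiseFrac > 0, noiseFrac < 1,
            singleThreshold > 0, singleThreshold <= 1)
  structure(list(peakHalfwidth = as.integer(peakHalfwidth),
                 flank = as.integer(flank), noiseFrac = noiseFrac,
                 singleThreshold = singleThreshold,
                 sizeClass = as.integer(sizeClass),
                 abundanceFlank = as.integer(abundanceFlank),
                 noiseCutDenominatorOnly = noiseCutDenominatorOnly),
            class = "classifierConfig")
}

#' Read an origin annotation BED
#'
#' BED columns chrom/start/end plus an optional 4th name column and an
#' optional 5th column holding the ACS (ARS consensus sequence) position.
#'
#' @param path BED path.
#' @param genome `Seqinfo` genome index.
#' @return `GRanges` with `name` (and `acsPos` when present).
#' @export
readOrigins <- function(path, genome) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  gr <- fragmentsGRanges(tab[[1]], tab[[2]], tab[[3]], genome)
  gr$name <- if (ncol(tab) >= 4) as.character(tab[[4]]) else
    paste0("origin_", seq_along(gr))
  if (ncol(tab) >= 5) gr$acsPos <- suppressWarnings(as.integer(tab[[5]]))
  gr
}

#' Locate the size-class signal peak in an origin's classification window
#'
#' The window is the annotated origin interval extended by `flank` bp on
#' each side (clipped to the chromosome). The peak is the position of
#' maximal depth; ties are broken toward the smallest coordinate.
#'
#' @param track Size-class `SignalTrack` (51-100 bp by default upstream).
#' @param origin One-row `GRanges`.
#' @param cfg A [classifierConfig()].
#' @return A list `ok`, `peakPos` (0-based), `peakHeight`; `ok = FALSE`
#'   flags a window with no signal.
#' @export
findPeak <- function(track, origin, cfg = classifierConfig()) {
  ch <- as.character(GenomicRanges::seqnames(origin))[1]
  w0 <- GenomicRanges::start(origin)[1] - 1L - cfg$flank
  w1 <- GenomicRanges::end(origin)[1] + cfg$flank
  sl <- lengths(trackValues(track))[[ch]]
  w0 <- max(0L, w0); w1 <- min(sl, w1)
  v <- trackWindow(track, ch, w0, w1)
  if (!length(v) || max(v) == 0)
    return(list(ok = FALSE, peakPos = NA_integer_, peakHeight = 0))
  i <- which.max(v)                      # first max = leftmost tie
  list(ok = TRUE, peakPos = w0 + i - 1L, peakHeight = v[i],
       windowStart = w0, windowEnd = w1)
}

#' Single-footprint fraction at one origin
#'
#' The fraction of supra-noise size-class signal in the classification
#' window that lies within `peakHalfwidth` bp of the peak. Per-bp depths
#' below `noiseFrac` x peak height are excluded as noise (from both sums by
#' default).
#'
#' @inheritParams findPeak
#' @return A list `ok`, `fraction`, `peakPos`, `peakHeight`.
#' @export
singleFraction <- function(track, origin, cfg = classifierConfig()) {
  pk <- findPeak(track, origin, cfg)
  if (!pk$ok) return(list(ok = FALSE, fraction = NA_real_,
                          peakPos = NA_integer_, peakHeight = 0))
  ch <- as.character(GenomicRanges::seqnames(origin))[1]
  v <- trackWindow(track, ch, pk$windowStart, pk$windowEnd)
  pos <- seq(pk$windowStart, pk$windowEnd - 1L)
  cut <- cfg$noiseFrac * pk$peakHeight
  supra <- v >= cut
  den <- sum(v[supra])
  inPeak <- abs(pos - pk$peakPos) <= cfg$peakHalfwidth
  num <- if (cfg$noiseCutDenominatorOnly) sum(v[inPeak]) else
    sum(v[inPeak & supra])
  if (den == 0) return(list(ok = FALSE, fraction = NA_real_,
                            peakPos = pk$peakPos, peakHeight = pk$peakHeight))
  list(ok = TRUE, fraction = num / den,
       peakPos = pk$peakPos, peakHeight = pk$peakHeight)
}

#' Total all-size signal around the origin center
#'
#' Sum of all-fragment-size depth over origin center +/- `abundanceFlank`
#' bp (1601 positions at the default), clipped at chromosome ends. The
#' center is the midpoint of the annotated interval.
#'
#' @param trackAll All-size `SignalTrack`.
#' @inheritParams findPeak
#' @return Numeric abundance.
#' @export
originAbundance <- function(trackAll, origin, cfg = classifierConfig()) {
  ch <- as.character(GenomicRanges::seqnames(origin))[1]
  s0 <- GenomicRanges::start(origin)[1] - 1L
  e0 <- GenomicRanges::end(origin)[1]
  center <- (s0 + e0) %/% 2L
  sum(trackWindow(trackAll, ch, center - cfg$abundanceFlank,
                  center + cfg$abundanceFlank + 1L))
}

#' Classify every origin as single- or multiple-footprint
#'
#' Applies [singleFraction()] and [originAbundance()] to each origin.
#' An origin is "single" iff its single-footprint fraction is at least
#' `singleThreshold` (0.80, inclusive). Origins with no supra-zero signal
#' in the window are flagged `no_signal` and excluded from classification.
#'
#' @param track Size-class `SignalTrack` (e.g. 51-100 bp).
#' @param trackAll All-size `SignalTrack` for abundance.
#' @param origins `GRanges` of origin annotations with `name`.
#' @param cfg A [classifierConfig()].
#' @param exclude Optional `GRanges`; origins overlapping it (e.g. rDNA or
#'   regions of mapping ambiguity) are dropped before classification.
#' @return A data.frame: name, chrom, peakPos, peakHeight, singleFraction,
#'   class ("single"/"multiple"/"no_signal"), abundance.
#' @export
classifyOrigins <- function(track, trackAll, origins, cfg = classifierConfig(),
                            exclude = NULL) {
  if (!is.null(exclude))
    origins <- origins[!IRanges::overlapsAny(origins, exclude)]
  n <- length(origins)
  out <- data.frame(
    name = origins$name,
    chrom = as.character(GenomicRanges::seqnames(origins)),
    peakPos = NA_integer_, peakHeight = NA_real_,
    singleFraction = NA_real_, class = "no_signal",
    abundance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    o <- origins[i]
    sf <- singleFraction(track, o, cfg)
    out$abundance[i] <- originAbundance(trackAll, o, cfg)
    if (!sf$ok) next
    out$peakPos[i] <- sf$peakPos
    out$peakHeight[i] <- sf$peakHeight
    out$singleFraction[i] <- sf$fraction
    out$class[i] <- if (sf$fraction >= cfg$singleThreshold) "single" else "multiple"
  }
  out
}

# internal: two-sample t test robust to zero-variance degenerate input
.safeTTest <- function(a, b, varEqual = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    return(list(t = NA_real_, p = NA_real_, diffCI = c(NA_real_, NA_real_),
                flag = "group too small"))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    d <- mean(a) - mean(b)
    if (d == 0) return(list(t = 0, p = 1, diffCI = c(0, 0),
                            flag = "constant groups"))
    return(list(t = Inf * sign(d), p = 0, diffCI = c(d, d),
                flag = "constant groups"))
  }
  tt <- stats::t.test(a, b, var.equal = varEqual)
  list(t = unname(tt$statistic), p = tt$p.value,
       diffCI = as.numeric(tt$conf.int), flag = NA_character_)
}

#' Compare abundance (and optional activity) between footprint classes
#'
#' Per-class n, mean and median of origin abundance, the cumulative share
#' of total signal per class, and a two-tailed unpaired t-test between the
#' classes (Welch by default; set `varEqual = TRUE` for the pooled form).
#'
#' @param calls data.frame from [classifyOrigins()].
#' @param activity Optional named numeric vector of per-origin activity
#'   scores (names matching `calls$name`).
#' @param varEqual Use the pooled-variance t test (default `FALSE`).
#' @return A list: `summary` data.frame (one row per class), `t`, `p`,
#'   and when `activity` is given, `activityT`, `activityP`.
#' @export
compareFootprintClasses <- function(calls, activity = NULL, varEqual = FALSE) {
  calls <- calls[calls$class %in% c("single", "multiple"), ]
  groups <- split(calls$abundance, calls$class)
  total <- sum(calls$abundance)
  summ <- do.call(rbind, lapply(names(groups), function(k) {
    g <- groups[[k]]
    data.frame(class = k, n = length(g), mean = mean(g),
               median = stats::median(g),
               signalShare = if (total > 0) sum(g) / total else NA_real_)
  }))
  res <- list(summary = summ)
  if (all(c("single", "multiple") %in% names(groups))) {
    tt <- .safeTTest(groups$single, groups$multiple, varEqual)
    res$t <- tt$t; res$p <- tt$p; res$flag <- tt$flag
  } else {
    res$t <- NA_real_; res$p <- NA_real_; res$flag <- "a class is empty"
  }
  if (!is.null(activity)) {
    act <- activity[calls$name]
    ag <- split(as.numeric(act), calls$class)
    if (all(c("single", "multiple") %in% names(ag))) {
      at <- .safeTTest(ag$single, ag$multiple, varEqual)
      res$activityT <- at$t; res$activityP <- at$p
      res$summary$activityMean <- vapply(res$summary$class,
        function(k) mean(ag[[k]]), 0)
    }
  }
  res
}

#' Write footprint calls as a TSV report
#'
#' @param calls data.frame from [classifyOrigins()].
#' @param path Output path.
#' @param cfg The [classifierConfig()] used; recorded in a commented header.
#' @export
writeFootprintCalls <- function(calls, path, cfg = classifierConfig()) {
  hdr <- sprintf(
    "# footprint calls | sizeClass=%d-%d peakHalfwidth=%d flank=%d noiseFrac=%g singleThreshold=%g abundanceFlank=%d noiseCutDenominatorOnly=%s",
    cfg$sizeClass[1], cfg$sizeClass[2], cfg$peakHalfwidth, cfg$flank,
    cfg$noiseFrac, cfg$singleThreshold, cfg$abundanceFlank,
    cfg$noiseCutDenominatorOnly)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
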