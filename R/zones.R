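#' Zone-calling configuration
#'
#' @param majorityThreshold Fork-direction fraction defining "majority"
#'   (default 0.5).
#' @param minSeparation Zones closer than this (bp) to the nearest
#'   opposite-kind zone are removed (default 5000).
#' @param comparisonBin Bin size (bp) for zone-signal comparisons
#'   (default 1000).
#' @return A list of class `zoneConfig`.
#' @export
zoneConfig <- function(majorityThreshold = 0.5, minSeparation = 5000L,
                       comparisonBin = 1000L) {
  stopifnot(minSeparation >= 0)
  structure(list(majorityThreshold = majorityThreshold,
                 minSeparation = as.integer(minSeparation),
                 comparisonBin = as.integer(comparisonBin)),
            class = "zoneConfig")
}

#' Call replication initiation and termination zones from a fork-direction track
#'
#' The track holds, per bin, the fraction of Watson-strand synthesis
#' attributed to pol delta (Pu-seq convention; equivalently 1 - fraction of
#' rightward-moving forks). A zone center is placed at every crossing of the
#' majority threshold, linearly interpolated between the two flanking bin
#' centers: downward crossings (delta-majority to epsilon-majority, left to
#' right) are initiation zones, upward crossings termination zones. Zones
#' closer than `minSeparation` to the nearest opposite-kind zone are then
#' removed (both members of a close pair; the removal is symmetric, so
#' focal-only removal gives the same set).
#'
#' @param forkTrack A `GRanges` of bins with a `score` column in `[0,1]`
#'   (pol-delta fraction); `NA` bins are skipped.
#' @param cfg A [zoneConfig()].
#' @return `GRanges` of 1-bp zone centers with `kind`
#'   ("initiation"/"termination"); empty with a warning on a constant
#'   track.
#' @export
callZones <- function(forkTrack, cfg = zoneConfig()) {
  th <- cfg$majorityThreshold
  ch <- as.character(GenomicRanges::seqnames(forkTrack))
  centers0 <- (GenomicRanges::start(forkTrack) - 1 +
                 GenomicRanges::end(forkTrack) - 1) / 2
  outCh <- character(0); outPos <- numeric(0); outKind <- character(0)
  for (c1 in unique(ch)) {
    idx <- which(ch == c1)
    d <- forkTrack$score[idx]; x <- centers0[idx]
    ok <- !is.na(d)
    d <- d[ok]; x <- x[ok]
    if (length(d) < 2) next
    s <- d >= th                          # TRUE = delta side (ties: delta)
    cross <- which(s[-length(s)] != s[-1])
    for (i in cross) {
      frac <- if (d[i + 1] == d[i]) 0.5 else (th - d[i]) / (d[i + 1] - d[i])
      pos <- x[i] + frac * (x[i + 1] - x[i])
      kind <- if (s[i]) "initiation" else "termination"  # downward = initiation
      outCh <- c(outCh, c1); outPos <- c(outPos, pos); outKind <- c(outKind, kind)
    }
  }
  if (!length(outPos)) {
    warning("no threshold crossings: constant or undefined track")
    return(GenomicRanges::GRanges(kind = character(0)))
  }
  zones <- GenomicRanges::GRanges(outCh,
    IRanges::IRanges(as.integer(round(outPos)) + 1L, width = 1L),
    kind = outKind)
  filterZonePairs(zones, cfg$minSeparation)
}

#' Remove zones too close to an opposite-kind zone
#'
#' @param zones `GRanges` with `kind`.
#' @param minSeparation Minimum bp to the nearest opposite-kind zone.
#' @return Filtered `GRanges`.
#' @export
filterZonePairs <- function(zones, minSeparation) {
  if (length(zones) < 2 || minSeparation <= 0) return(zones)
  drop <- rep(FALSE, length(zones))
  ch <- as.character(GenomicRanges::seqnames(zones))
  pos <- GenomicRanges::start(zones)
  for (i in seq_along(zones)) {
    opp <- which(ch == ch[i] & zones$kind != zones$kind[i])
    if (length(opp) && min(abs(pos[opp] - pos[i])) < minSeparation)
      drop[i] <- TRUE
  }
  zones[!drop]
}

#' Compare binned signal between initiation and termination zones
#'
#' Bins overlapping initiation-zone centers (or supplied zone extents) form
#' one group, bins overlapping termination zones the other; bins touching
#' both kinds are excluded as ambiguous. With a control track the per-bin
#' ratio signal/control is compared instead (control-zero bins dropped) -
#' e.g. MCM ChEC over sonicated G1 DNA. Reports group means with 95%
#' confidence intervals, the percent excess of the initiation mean over the
#' termination mean, and a two-tailed unpaired t test (Welch by default).
#'
#' @param signal `GRanges` of bins with `score` (typically 1 kb bins).
#' @param zones `GRanges` with `kind`; widths > 1 are treated as extents.
#' @param control Optional `GRanges` of bins with `score`, same binning.
#' @param varEqual Pooled-variance t test if `TRUE`.
#' @return A list: `summary` (per-group n/mean/ci), `percentExcess` with its
#'   95% CI `percentExcessCI`, `t`, `p`, `flag`.
#' @export
compareZoneSignal <- function(signal, zones, control = NULL, varEqual = FALSE) {
  x <- signal$score
  if (!is.null(control)) {
    if (length(control) != length(signal)) stop("control binning differs")
    keep <- control$score > 0
    signal <- signal[keep]
    x <- x[keep] / control$score[keep]
  }
  initHit <- IRanges::overlapsAny(signal, zones[zones$kind == "initiation"])
  termHit <- IRanges::overlapsAny(signal, zones[zones$kind == "termination"])
  gInit <- x[initHit & !termHit]
  gTerm <- x[termHit & !initHit]
  .zoneGroupReport(gInit, gTerm, varEqual,
                   labels = c("initiation", "termination"))
}

# internal: two-group report with CIs and percent excess of group1 over group2
.zoneGroupReport <- function(g1, g2, varEqual, labels) {
  ci <- function(g) {
    if (length(g) < 2) return(c(NA_real_, NA_real_))
    se <- stats::sd(g) / sqrt(length(g))
    mean(g) + c(-1, 1) * stats::qt(0.975, length(g) - 1) * se
  }
  summ <- data.frame(group = labels,
                     n = c(length(g1), length(g2)),
                     mean = c(mean(g1), mean(g2)),
                     ciLow = c(ci(g1)[1], ci(g2)[1]),
                     ciHigh = c(ci(g1)[2], ci(g2)[2]))
  if (length(g1) == 0 || length(g2) == 0)
    return(list(summary = summ, percentExcess = NA_real_,
                percentExcessCI = c(NA_real_, NA_real_), t = NA_real_,
                p = NA_real_, flag = "a group is empty"))
  tt <- .safeTTest(g1, g2, varEqual)
  list(summary = summ,
       percentExcess = 100 * (mean(g1) - mean(g2)) / mean(g2),
       percentExcessCI = 100 * tt$diffCI / mean(g2),
       t = tt$t, p = tt$p, flag = tt$flag)
}

#' Compare signal in peak-overlapping bins vs their immediate neighbors
#'
#' Bins overlapping the supplied peak intervals form one group; the bins
#' immediately to the left and right of each run of overlapping bins form
#' the other (neighbors that themselves overlap a peak are excluded;
#' chromosome-edge runs contribute their single existing neighbor).
#'
#' @param signal `GRanges` of bins with `score`.
#' @param peaks `GRanges` of peak intervals.
#' @param varEqual Pooled-variance t test if `TRUE`.
#' @return As [compareZoneSignal()], with groups "peak" and "adjacent".
#' @export
peakAdjacentTest <- function(signal, peaks, varEqual = FALSE) {
  hit <- IRanges::overlapsAny(signal, peaks)
  ch <- as.character(GenomicRanges::seqnames(signal))
  nbr <- rep(FALSE, length(signal))
  for (c1 in unique(ch)) {
    idx <- which(ch == c1)
    h <- hit[idx]
    r <- rle(h)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      if (starts[j] > 1L) nbr[idx[starts[j] - 1L]] <- TRUE
      if (ends[j] < length(h)) nbr[idx[ends[j] + 1L]] <- TRUE
    }
  }
  nbr <- nbr & !hit
  .zoneGroupReport(signal$score[hit], signal$score[nbr], varEqual,
                   labels = c("peak", "adjacent"))
}

#' Read a fork-direction (polymerase-usage) track
#'
#' Accepts a wig.bed-like TSV: chrom, bin start (0-based), value, with an
#' optional 4th column taken as the bin end. Without an end column, bin
#' widths are inferred from the start spacing per chromosome.
#'
#' @param path TSV path.
#' @param genome Optional `Seqinfo`.
#' @return `GRanges` of bins with `score`.
#' @export
readForkTrack <- function(path, genome = NULL) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  chrom <- as.character(tab[[1]]); start0 <- as.numeric(tab[[2]])
  if (ncol(tab) >= 4 && is.numeric(tab[[3]])) {
    # chrom start end value (bedGraph dialect)
    end0 <- as.numeric(tab[[3]]); val <- as.numeric(tab[[4]])
  } else {
    val <- as.numeric(tab[[3]])
    end0 <- start0
    for (c1 in unique(chrom)) {
      idx <- which(chrom == c1)
      step <- if (length(idx) > 1) stats::median(diff(sort(start0[idx]))) else 1
      end0[idx] <- start0[idx] + step
    }
  }
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(as.integer(start0) + 1L, as.integer(end0)), score = val)
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  gr
}

#' Write zones as BED6 (kind in the name field)
#'
#' @param zones `GRanges` with `kind`.
#' @param path Output path.
#' @export
writeZones <- function(zones, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(zones)),
    start = GenomicRanges::start(zones) - 1L,
    end = GenomicRanges::end(zones),
    name = zones$kind, score = 0L, strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
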