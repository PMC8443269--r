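#' Build a per-base-pair coverage track, optionally for one size class
#'
#' Every retained fragment adds +1 to every base pair it covers, so the
#' total track mass equals the summed lengths of retained fragments.
#' An alternative midpoint mode assigns each fragment's full weight to its
#' single midpoint base.
#'
#' @param fragments `GRanges` of fragments with a complete `Seqinfo`.
#' @param sizeClass `NULL` / `"all"` for all fragment sizes, or a length-2
#'   numeric `c(min, max)` of inclusive length bounds in bp. The MCM
#'   double-hexamer class defaults used elsewhere are 51-100 bp; the
#'   nucleosomal class is 151-200 bp.
#' @param mode `"coverage"` (default) or `"midpoint"`.
#' @return A [SignalTrack-class].
#' @examples
#' gi <- genomeIndex("chr1", 1000L)
#' fr <- fragmentsGRanges("chr1", 100L, 160L, gi)
#' tr <- coverageTrack(fr)
#' trackMass(tr)  # 60
#' @export
coverageTrack <- function(fragments, sizeClass = NULL, mode = c("coverage", "midpoint")) {
  mode <- match.arg(mode)
  sc <- normalizeSizeClass(sizeClass)
  if (length(sc)) {
    w <- GenomicRanges::width(fragments)
    fragments <- fragments[w >= sc[1] & w <= sc[2]]
  }
  if (mode == "midpoint" && length(fragments)) {
    mid <- GenomicRanges::start(fragments) +
      (GenomicRanges::width(fragments) - 1L) %/% 2L
    fragments <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(fragments),
      IRanges::IRanges(mid, width = 1L),
      seqinfo = GenomicRanges::seqinfo(fragments))
  }
  cov <- GenomicRanges::coverage(fragments)
  new("SignalTrack", values = cov, sizeClass = sc)
}

# internal: accept NULL, "all", or c(min, max)
normalizeSizeClass <- function(sizeClass) {
  if (is.null(sizeClass) || identical(sizeClass, "all")) return(integer(0))
  sc <- as.integer(sizeClass)
  if (length(sc) != 2 || sc[1] < 1L || sc[1] > sc[2])
    stop("sizeClass must be NULL/\"all\" or c(min, max) with 1 <= min <= max")
  sc
}

#' Origin-centered fragment-length x position heat matrix
#'
#' A fragment of length L contributes +1 to row L at every column whose
#' genomic position the fragment covers, clipped to the window; fragments
#' longer than `maxFragLen` are dropped. With the defaults the result is the
#' 500 x 3001 per-base-pair depth matrix used for the virtual-gel heat maps.
#'
#' @param fragments `GRanges` of fragments.
#' @param chrom Chromosome of the window center.
#' @param center 0-based center position.
#' @param halfWindow Window half-width in bp (default 1500).
#' @param maxFragLen Largest fragment length kept as a row (default 500).
#' @return A [HeatMatrix-class].
#' @export
heatMatrix <- function(fragments, chrom, center, halfWindow = 1500L,
                       maxFragLen = 500L) {
  halfWindow <- as.integer(halfWindow); maxFragLen <- as.integer(maxFragLen)
  center <- as.integer(center)
  sl <- .chromLengths(GenomicRanges::seqinfo(fragments))
  if (!chrom %in% names(sl)) stop("unknown chromosome: ", chrom)
  if (center - halfWindow < 0L || center + halfWindow >= sl[[chrom]])
    stop("window exceeds chromosome bounds")
  win0 <- center - halfWindow          # 0-based window start
  ncols <- 2L * halfWindow + 1L
  cells <- matrix(0, nrow = maxFragLen, ncol = ncols)
  onChrom <- as.character(GenomicRanges::seqnames(fragments)) == chrom
  fr <- fragments[onChrom]
  s0 <- GenomicRanges::start(fr) - 1L   # 0-based starts
  e0 <- GenomicRanges::end(fr)          # 0-based exclusive ends
  L <- GenomicRanges::width(fr)
  keep <- L <= maxFragLen & e0 > win0 & s0 < win0 + ncols
  s0 <- s0[keep]; e0 <- e0[keep]; L <- L[keep]
  a <- pmax(s0, win0) - win0 + 1L       # first column (1-based)
  b <- pmin(e0, win0 + ncols) - win0    # last column
  for (i in seq_along(L)) cells[L[i], a[i]:b[i]] <- cells[L[i], a[i]:b[i]] + 1
  new("HeatMatrix", cells = cells, chrom = chrom, center = center,
      halfWindow = halfWindow, maxFragLen = maxFragLen)
}

#' Sum a heat matrix over a fragment-length band
#'
#' The row-band sum over lengths `min..max` reproduces, within the window,
#' the per-bp coverage of the corresponding size class exactly.
#'
#' @param matrix A `HeatMatrix`.
#' @param sizeClass Length-2 inclusive bounds, or `NULL`/"all".
#' @return Numeric vector of per-position depths (length `2*halfWindow+1`).
#' @export
bandCoverage <- function(matrix, sizeClass = NULL) {
  sc <- normalizeSizeClass(sizeClass)
  rows <- if (length(sc)) seq(sc[1], min(sc[2], matrix@maxFragLen)) else
    seq_len(matrix@maxFragLen)
  colSums(matrix@cells[rows, , drop = FALSE])
}

#' Render a heat matrix to a PNG with optional depth cap
#'
#' Cell intensities are clipped at `cap` before color mapping (a high cap
#' hides weak footprints; the true maximum is preserved alongside). The cap
#' and the true maximum are recorded in a TSV sidecar next to the image.
#'
#' @param matrix A `HeatMatrix`.
#' @param path Output PNG path; the sidecar is written to `<path>.meta.tsv`.
#' @param cap Depth cap (> 0) or `NULL` for a linear scale to the true max.
#' @return Invisibly, a list with `cap`, `max` and the two file paths.
#' @export
renderHeatmap <- function(matrix, path, cap = NULL) {
  if (!is.null(cap) && cap <= 0) stop("cap must be > 0")
  cells <- matrix@cells
  trueMax <- max(cells)
  if (!is.null(cap)) cells <- pmin(cells, cap)
  top <- if (is.null(cap)) max(trueMax, 1) else cap
  grDevices::png(path, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("black", "darkblue", "cyan", "white"))(256)
  graphics::image(
    x = seq(-matrix@halfWindow, matrix@halfWindow),
    y = seq_len(matrix@maxFragLen),
    z = t(cells), zlim = c(0, top), col = pal,
    xlab = paste0("position relative to ", matrix@chrom, ":", matrix@center),
    ylab = "fragment length (bp)", useRaster = TRUE)
  meta <- data.frame(cap = if (is.null(cap)) NA else cap, max_depth = trueMax,
                     chrom = matrix@chrom, center = matrix@center)
  sidecar <- paste0(path, ".meta.tsv")
  utils::write.table(meta, sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(cap = cap, max = trueMax, image = path, sidecar = sidecar))
}

#' Extract a per-bp window from a SignalTrack as a numeric vector
#'
#' @param track A `SignalTrack`.
#' @param chrom Chromosome.
#' @param start0 0-based inclusive start.
#' @param end0 0-based exclusive end (clipped to the chromosome).
#' @return Numeric vector of depths.
#' @export
trackWindow <- function(track, chrom, start0, end0) {
  v <- trackValues(track)[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  s <- max(0L, as.integer(start0)); e <- min(length(v), as.integer(end0))
  if (e <= s) return(numeric(0))
  as.numeric(v[(s + 1L):e])
}

#' Export a SignalTrack (or binned signal) as bedGraph
#'
#' @param x A `SignalTrack` or a `GRanges` with a `score` column.
#' @param path Output path.
#' @export
writeBedGraph <- function(x, path) {
  if (is(x, "SignalTrack")) {
    gr <- GenomicRanges::bindAsGRanges(score = trackValues(x))
  } else gr <- x
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Import a bedGraph as a GRanges with a score column
#'
#' @param path bedGraph path.
#' @param genome Optional `Seqinfo` to attach.
#' @return A `GRanges` with `score`.
#' @export
readBedGraph <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  gr
}
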