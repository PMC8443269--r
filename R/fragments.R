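#' Read a paired-end fragment table (BED3-like TSV) into a GRanges
#'
#' Each line is one sequenced fragment as `chrom<TAB>start<TAB>end` with
#' 0-based half-open coordinates (native BED). Records are validated against
#' the genome index; malformed lines are reported with their line numbers.
#'
#' @param path Path to the fragment table. Lines starting with `#` or
#'   `track` are skipped.
#' @param genome A `Seqinfo` genome index covering every chromosome in the
#'   file.
#' @return A [GenomicRanges::GRanges] of fragments (1-based closed
#'   internally, as is native to GRanges; widths equal fragment lengths).
#' @export
readFragments <- function(path, genome) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- lineno[nf < 3]
    stop("malformed fragment line(s) (need >= 3 tab-separated fields) at line(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- lineno[is.na(start) | is.na(end)]
    stop("non-numeric coordinates at line(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  fragmentsGRanges(chrom, start, end, genome, lineno = lineno)
}

#' Construct a validated fragment GRanges from 0-based half-open coordinates
#'
#' Shared constructor behind [readFragments()] and the synthetic generator.
#'
#' @param chrom,start,end Parallel vectors; `start`/`end` 0-based half-open.
#' @param genome `Seqinfo` genome index.
#' @param lineno Optional source line numbers used in error messages.
#' @return A `GRanges` with `seqinfo` set.
#' @export
fragmentsGRanges <- function(chrom, start, end, genome, lineno = NULL) {
  sl <- .chromLengths(genome)
  unknown <- !(chrom %in% names(sl))
  if (any(unknown)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[unknown]), collapse = ", "))
  }
  bad <- end <= start
  if (any(bad)) {
    where <- if (is.null(lineno)) which(bad) else lineno[bad]
    stop("end before (or equal to) start at line(s)/record(s): ",
         paste(utils::head(where, 10), collapse = ", "))
  }
  oob <- start < 0L | end > sl[chrom]
  if (any(oob)) {
    where <- if (is.null(lineno)) which(oob) else lineno[oob]
    stop("coordinates outside chromosome bounds at line(s)/record(s): ",
         paste(utils::head(where, 10), collapse = ", "))
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end),
                         seqinfo = genome)
}

#' Write fragments back to a BED3 TSV (lossless round-trip)
#'
#' @param fragments A `GRanges` of fragments.
#' @param path Output path.
#' @export
writeFragments <- function(fragments, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(fragments)),
    start = GenomicRanges::start(fragments) - 1L,
    end = GenomicRanges::end(fragments))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fragment-length histogram and modal length
#'
#' ChEC libraries from MNase-tagged MCM subunits are bimodal: a short mode
#' near 60 bp (the DNA protected by one MCM double hexamer) and a
#' nucleosomal mode in the 150-200 bp band.
#'
#' @param fragments A `GRanges` of fragments (nonempty).
#' @param maxLen Largest length tabulated (default 500).
#' @return A list with `counts` (named integer vector for lengths
#'   1..`maxLen`), `mode` (smallest length attaining the maximum count) and
#'   `n` (fragments of length <= `maxLen`).
#' @export
fragmentLengthHistogram <- function(fragments, maxLen = 500L) {
  if (length(fragments) == 0) stop("no fragments")
  w <- GenomicRanges::width(fragments)
  w <- w[w <= maxLen]
  counts <- tabulate(w, nbins = maxLen)
  names(counts) <- seq_len(maxLen)
  list(counts = counts, mode = unname(which.max(counts)), n = sum(counts))
}
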