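#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importClassesFrom IRanges RleList
NULL

#' SignalTrack: per-base-pair read depth over a genome
#'
#' A thin S4 container around an [IRanges::RleList] of per-base-pair depths,
#' one run-length-encoded vector per chromosome, optionally restricted to a
#' sequenced-fragment size class. ChEC libraries are fragment-size mixtures:
#' the ~60 bp MCM double-hexamer footprint lives in short fragments while
#' flanking nucleosomes produce 150-200 bp fragments, so most analyses start
#' by splitting coverage by size class.
#'
#' @slot values An `RleList` of non-negative per-bp depths; one element per
#'   chromosome, each of length equal to the chromosome length.
#' @slot sizeClass Integer vector of length 2 (inclusive min/max fragment
#'   length in bp) or length 0 for "all fragment sizes".
#'
#' @seealso [coverageTrack()], [binTrack()]
#' @export
setClass("SignalTrack",
  representation(values = "RleList", sizeClass = "integer"))

setValidity("SignalTrack", function(object) {
  msg <- NULL
  if (length(object@sizeClass) != 0 && length(object@sizeClass) != 2)
    msg <- c(msg, "sizeClass must have length 0 (all sizes) or 2 (min,max)")
  if (length(object@sizeClass) == 2) {
    if (object@sizeClass[1] < 1L || object@sizeClass[1] > object@sizeClass[2])
      msg <- c(msg, "sizeClass must satisfy 1 <= min <= max")
  }
  if (length(object@values)) {
    mins <- vapply(object@values, function(v) min(S4Vectors::runValue(v), 0), 0)
    if (any(mins < 0)) msg <- c(msg, "depths must be non-negative")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SignalTrack-class Per-chromosome depth vectors (`RleList`).
#' @param x,object A `SignalTrack`.
#' @export
trackValues <- function(x) x@values

#' @describeIn SignalTrack-class Fragment size class (integer `c(min, max)`,
#'   or `integer(0)` for all sizes).
#' @export
sizeClass <- function(x) x@sizeClass

#' @describeIn SignalTrack-class Total depth mass (sum over all bp).
#' @export
trackMass <- function(x) sum(vapply(x@values, function(v) sum(as.numeric(v)), 0))

setMethod("show", "SignalTrack", function(object) {
  sc <- if (length(object@sizeClass)) {
    paste0(object@sizeClass[1], "-", object@sizeClass[2], " bp")
  } else "all sizes"
  cat("SignalTrack (", sc, ") over ", length(object@values),
      " chromosome(s); total mass ", format(trackMass(object)), "\n", sep = "")
})

#' HeatMatrix: origin-centered fragment-length x position depth matrix
#'
#' The "virtual gel" view of a ChEC library around one genomic position:
#' rows are fragment lengths 1..`maxFragLen`, columns are genomic offsets
#' -`halfWindow`..+`halfWindow` relative to `center`, and each cell holds the
#' per-base-pair read depth contributed by fragments of that exact length.
#' With the defaults (half-window 1500 bp, fragment lengths up to 500 bp)
#' the matrix is 500 x 3001.
#'
#' @slot cells Numeric matrix, `maxFragLen` rows x `2*halfWindow + 1` columns.
#' @slot chrom Chromosome of the center position.
#' @slot center 0-based center position.
#' @slot halfWindow Window half-width in bp.
#' @slot maxFragLen Largest fragment length retained (rows beyond are dropped).
#'
#' @seealso [heatMatrix()], [renderHeatmap()], [bandCoverage()]
#' @export
setClass("HeatMatrix",
  representation(cells = "matrix", chrom = "character", center = "integer",
                 halfWindow = "integer", maxFragLen = "integer"))

setValidity("HeatMatrix", function(object) {
  msg <- NULL
  if (nrow(object@cells) != object@maxFragLen)
    msg <- c(msg, "cells must have maxFragLen rows")
  if (ncol(object@cells) != 2L * object@halfWindow + 1L)
    msg <- c(msg, "cells must have 2*halfWindow + 1 columns")
  if (any(object@cells < 0)) msg <- c(msg, "cells must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn HeatMatrix-class The raw cell matrix (rows = fragment length).
#' @param x,object A `HeatMatrix`.
#' @export
heatCells <- function(x) x@cells

setMethod("show", "HeatMatrix", function(object) {
  cat("HeatMatrix ", nrow(object@cells), " x ", ncol(object@cells),
      " centered at ", object@chrom, ":", object@center,
      " (half-window ", object@halfWindow, " bp)\n", sep = "")
})
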