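#' Build a genome index from chromosome names and lengths
#'
#' The genome index is a [GenomeInfoDb::Seqinfo]: the ordered chromosome
#' names and lengths against which all coordinates are validated. All
#' coordinates in this package are 0-based, half-open internally; BED-style
#' input is therefore consumed natively and 1-based input must be converted
#' at the boundary.
#'
#' @param chromNames Character vector of unique chromosome identifiers.
#' @param chromLengths Integer vector of chromosome lengths (bp, > 0).
#' @return A `Seqinfo` object.
#' @examples
#' gi <- genomeIndex(c("chrI", "chrII"), c(230218L, 813184L))
#' @export
genomeIndex <- function(chromNames, chromLengths) {
  if (anyDuplicated(chromNames)) stop("chromosome names must be unique")
  if (any(chromLengths <= 0)) stop("chromosome lengths must be positive")
  GenomeInfoDb::Seqinfo(seqnames = as.character(chromNames),
                        seqlengths = as.integer(chromLengths))
}

#' Read a genome index from a FASTA index (.fai) or FASTA file
#'
#' @param path Path to a `.fai` file (two or more tab-separated columns:
#'   name, length, ...) or to a FASTA file (read with
#'   [Biostrings::readDNAStringSet]).
#' @return A `Seqinfo` object.
#' @export
readGenomeIndex <- function(path) {
  if (grepl("\\.fai$", path)) {
    tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    genomeIndex(tab[[1]], tab[[2]])
  } else {
    seqs <- Biostrings::readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    genomeIndex(names(seqs), Biostrings::width(seqs))
  }
}

# internal: seqlengths as a named integer vector, erroring on missing lengths
.chromLengths <- function(seqinfo) {
  sl <- GenomeInfoDb::seqlengths(seqinfo)
  if (any(is.na(sl))) stop("genome index has chromosomes with unknown length")
  sl
}
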