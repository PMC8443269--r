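# Shared in-code fixtures: small deterministic genomes, fragment sets and
# tracks built at test time (no files shipped).

fixtureGenome <- function(chroms = c(chrA = 100000L)) {
  genomeIndex(names(chroms), chroms)
}

# n stacked fragments of the same interval -> depth n plateau
stackFragments <- function(chrom, start0, end0, n, genome) {
  fragmentsGRanges(rep(chrom, n), rep(start0, n), rep(end0, n), genome)
}

# random fragment set with reproducible layout
randomFragments <- function(n, genome, seed = 99, lenRange = c(40L, 250L)) {
  set.seed(seed)
  sl <- GenomeInfoDb::seqlengths(genome)
  chrom <- sample(names(sl), n, replace = TRUE)
  len <- sample(seq(lenRange[1], lenRange[2]), n, replace = TRUE)
  start0 <- vapply(seq_len(n),
                   function(i) sample.int(sl[[chrom[i]]] - len[i], 1) - 1L, 0L)
  fragmentsGRanges(chrom, start0, start0 + len, genome)
}

# one-row origin annotation
originAt <- function(chrom, start0, end0, genome, name = "oriTest") {
  o <- fragmentsGRanges(chrom, start0, end0, genome)
  o$name <- name
  o
}

# fork-direction track from explicit 1-bp bins at given 0-based positions
forkPoints <- function(chrom, pos0, delta) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1L, width = 1L),
                         score = delta)
}

# single-chromosome licensing field with all mass in chosen bins
pointField <- function(L, centers0, mass = NULL, binSize = 1000L,
                       chrom = "simChr") {
  gi <- genomeIndex(chrom, L)
  n <- length(centers0)
  if (is.null(mass)) mass <- rep(100L, n)
  frags <- fragmentsGRanges(rep(chrom, sum(mass)),
                            rep(centers0 - 5L, times = mass),
                            rep(centers0 + 5L, times = mass), gi)
  buildLicensingField(coverageTrack(frags), simConfig(binSize = binSize))
}
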