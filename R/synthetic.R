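#' Synthetic-data generator configuration
#'
#' Configures every synthetic input the pipeline can consume: genome,
#' licensing landscape, ChEC fragment library, fork-direction and S/G1
#' tracks, and hybrid SNP reads, all reproducible from `seed`. The
#' defaults emulate the study conditions at desk scale: a 2 Mb genome
#' carrying 200 origins and a 200,000-fragment ChEC library whose
#' protected cores are ~60 bp (sd 4) and whose flanking nucleosomal
#' fragments span 150-200 bp, with SNPs every ~75 bp for the hybrid
#' analyses.
#'
#' @param seed RNG seed (integer).
#' @param chromLengths Named integer vector of chromosome lengths.
#' @param nOrigins Number of origins (placed on a jittered regular grid).
#' @param landscapeMode `"focused"` (one or two discrete MCM sites per
#'   origin, budding-yeast-like) or `"dispersed"` (4-12 sub-sites spread
#'   over 500-1500 bp per origin, fission-yeast/human-like).
#' @param licensingProb Per-origin licensing probability (recycled to
#'   `nOrigins`); default 0.9.
#' @param compositeFraction Fraction of origins planted as two-site
#'   composites (focused mode; default 0).
#' @param compositeOffset bp between the two composite sub-sites
#'   (default 200).
#' @param coreLenMean,coreLenSd Protected-core fragment length model
#'   (truncated normal; defaults 60 and 4).
#' @param nucLenRange Nucleosomal fragment length range (default 150-200).
#' @param backgroundFraction Fraction of library fragments scattered
#'   uniformly as background (default 0.05).
#' @param fragmentCount Library size (default 200000).
#' @param atBias Couple genome AT content to origin positions: 0 for a
#'   uniform base composition, > 0 plants AT-rich islands at origins.
#' @param atBackground Genome-wide AT fraction away from islands
#'   (default 0.62, budding-yeast-like).
#' @param snpDensity Mean bp between SNPs (default 75; spacing drawn
#'   uniformly from 50-100 at the default).
#' @param readLength Hybrid read length (default 150).
#' @param nReads Hybrid reads generated (default 20000).
#' @param errorRate Per-base substitution error rate in hybrid reads
#'   (default 0).
#' @param sseqDepth Mean per-bin read count for synthetic S/G1 tracks
#'   (default 500, i.e. well-covered 1 kb bins as in a typical yeast
#'   S-seq library).
#' @return A list of class `synthConfig`.
#' @export
synthConfig <- function(seed = 1L,
                        chromLengths = c(synChrI = 1000000L, synChrII = 1000000L),
                        nOrigins = 200L,
                        landscapeMode = c("focused", "dispersed"),
                        licensingProb = 0.9,
                        compositeFraction = 0,
                        compositeOffset = 200L,
                        coreLenMean = 60, coreLenSd = 4,
                        nucLenRange = c(150L, 200L),
                        backgroundFraction = 0.05,
                        fragmentCount = 200000L,
                        atBias = 1,
                        atBackground = 0.62,
                        snpDensity = 75L,
                        readLength = 150L,
                        nReads = 20000L,
                        errorRate = 0,
                        sseqDepth = 500) {
  landscapeMode <- match.arg(landscapeMode)
  stopifnot(all(licensingProb >= 0 & licensingProb <= 1),
            compositeFraction >= 0, compositeFraction <= 1,
            coreLenMean > 0, backgroundFraction >= 0, backgroundFraction < 1)
  structure(list(seed = as.integer(seed), chromLengths = chromLengths,
                 nOrigins = as.integer(nOrigins), landscapeMode = landscapeMode,
                 licensingProb = licensingProb,
                 compositeFraction = compositeFraction,
                 compositeOffset = as.integer(compositeOffset),
                 coreLenMean = coreLenMean, coreLenSd = coreLenSd,
                 nucLenRange = as.integer(nucLenRange),
                 backgroundFraction = backgroundFraction,
                 fragmentCount = as.integer(fragmentCount),
                 atBias = atBias, atBackground = atBackground,
                 snpDensity = as.integer(snpDensity),
                 readLength = as.integer(readLength),
                 nReads = as.integer(nReads), errorRate = errorRate,
                 sseqDepth = sseqDepth),
            class = "synthConfig")
}

# deterministic origin layout: one origin per grid slot, jittered; returns
# data.frame(name, chrom, pos) with pos the (central) site position, plus a
# list column of sub-site positions per origin
.placeOrigins <- function(cfg) {
  set.seed(cfg$seed + 11L)
  sl <- cfg$chromLengths
  nPer <- pmax(1L, round(cfg$nOrigins * sl / sum(sl)))
  # adjust rounding so the total matches
  while (sum(nPer) > cfg$nOrigins) nPer[which.max(nPer)] <- nPer[which.max(nPer)] - 1L
  while (sum(nPer) < cfg$nOrigins) nPer[which.min(nPer)] <- nPer[which.min(nPer)] + 1L
  rows <- list()
  for (ci in seq_along(sl)) {
    n <- nPer[ci]; L <- sl[[ci]]
    spacing <- L %/% (n + 1L)
    base <- spacing * seq_len(n)
    jit <- as.integer(round(stats::runif(n, -spacing / 5, spacing / 5)))
    pos <- as.integer(pmin(pmax(base + jit, 2000L), L - 2000L))
    rows[[ci]] <- data.frame(chrom = names(sl)[ci], pos = pos)
  }
  out <- do.call(rbind, rows)
  out$name <- sprintf("origin_%03d", seq_len(nrow(out)))
  out
}

# sub-site positions per origin according to landscape mode / composites
.originSites <- function(cfg, layout) {
  set.seed(cfg$seed + 13L)
  n <- nrow(layout)
  lic <- rep(cfg$licensingProb, length.out = n)
  composite <- rep(FALSE, n)
  if (cfg$landscapeMode == "focused" && cfg$compositeFraction > 0) {
    nComp <- round(cfg$compositeFraction * n)
    composite[seq_len(nComp)] <- TRUE     # deterministic: first nComp origins
  }
  sites <- vector("list", n)
  for (i in seq_len(n)) {
    if (cfg$landscapeMode == "dispersed") {
      k <- sample(4:12, 1)
      span <- sample(500:1500, 1)
      sites[[i]] <- layout$pos[i] +
        as.integer(round(stats::runif(k, -span / 2, span / 2)))
    } else if (composite[i]) {
      sites[[i]] <- layout$pos[i] +
        as.integer(c(-cfg$compositeOffset %/% 2L, cfg$compositeOffset -
                       cfg$compositeOffset %/% 2L))
    } else {
      sites[[i]] <- layout$pos[i]
    }
  }
  list(licensing = lic, composite = composite, sites = sites)
}

#' Generate a synthetic genome (FASTA-ready DNAStringSet + index)
#'
#' Random sequence at `atBackground` AT fraction; when `atBias > 0`,
#' 200 bp AT-rich islands (90% AT) are planted at every origin position so
#' AT-coupled licensing analyses have signal to find.
#'
#' @param cfg A [synthConfig()].
#' @return A list: `seq` (`DNAStringSet`), `genome` (`Seqinfo`), `origins`
#'   (layout data.frame).
#' @export
makeGenome <- function(cfg = synthConfig()) {
  layout <- .placeOrigins(cfg)
  set.seed(cfg$seed + 17L)
  at <- cfg$atBackground
  pr <- c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)
  seqs <- lapply(names(cfg$chromLengths), function(c1) {
    L <- cfg$chromLengths[[c1]]
    bases <- sample(c("A", "T", "G", "C"), L, replace = TRUE, prob = pr)
    if (cfg$atBias > 0) {
      for (p in layout$pos[layout$chrom == c1]) {
        idx <- max(1L, p - 99L):min(L, p + 100L)
        bases[idx] <- sample(c("A", "T", "G", "C"), length(idx),
                             replace = TRUE, prob = c(0.45, 0.45, 0.05, 0.05))
      }
    }
    paste(bases, collapse = "")
  })
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- names(cfg$chromLengths)
  list(seq = dss, genome = genomeIndex(names(cfg$chromLengths),
                                       cfg$chromLengths),
       origins = layout)
}

#' Generate a synthetic ChEC fragment library with ground truth
#'
#' Each non-background fragment is attributed to an origin (weighted by its
#' licensing probability) and drawn either from the ~60 bp protected core
#' at one of the origin's sub-sites or from a flanking nucleosome
#' (150-200 bp, offset ~30-50 bp beyond the core edge). Composite origins
#' mix two sub-sites 50:50 across draws; background fragments are scattered
#' uniformly with lengths 50-250 bp.
#'
#' @param cfg A [synthConfig()].
#' @return A list: `fragments` (`GRanges`), `origins` (annotation `GRanges`
#'   with `name`), `truth` (data.frame name/chrom/pos/licensingProb/
#'   plantedClass), `genome` (`Seqinfo`).
#' @export
makeChecLibrary <- function(cfg = synthConfig()) {
  layout <- .placeOrigins(cfg)
  mode <- .originSites(cfg, layout)
  genome <- genomeIndex(names(cfg$chromLengths), cfg$chromLengths)
  sl <- cfg$chromLengths
  set.seed(cfg$seed + 19L)
  n <- cfg$fragmentCount
  # dispersed landscapes carry substantial inter-origin licensing: a large
  # share of fragments is scattered genome-wide, not just spread within
  # clusters, so chromosome-scale dispersion statistics see the contrast
  bgFrac <- if (cfg$landscapeMode == "dispersed")
    max(cfg$backgroundFraction, 0.4) else cfg$backgroundFraction
  nBg <- round(bgFrac * n)
  nOr <- n - nBg
  oIdx <- sample.int(nrow(layout), nOr, replace = TRUE, prob = mode$licensing)
  # pick one sub-site per fragment
  siteOf <- as.integer(vapply(oIdx, function(i) {
    s <- mode$sites[[i]]
    if (length(s) == 1) s else sample(s, 1)
  }, 0))
  chromOf <- layout$chrom[oIdx]
  isCore <- stats::runif(nOr) < 1 / 3
  len <- integer(nOr); center <- integer(nOr)
  nc <- sum(isCore)
  len[isCore] <- pmin(pmax(as.integer(round(stats::rnorm(nc, cfg$coreLenMean,
                                                         cfg$coreLenSd))), 40L), 90L)
  center[isCore] <- siteOf[isCore] +
    as.integer(round(stats::rnorm(nc, 0, 2)))
  nn <- nOr - nc
  len[!isCore] <- sample(seq(cfg$nucLenRange[1], cfg$nucLenRange[2]), nn,
                         replace = TRUE)
  side <- sample(c(-1L, 1L), nn, replace = TRUE)
  offset <- 30L + len[!isCore] %/% 2L +
    as.integer(round(stats::runif(nn, 0, 20)))
  center[!isCore] <- siteOf[!isCore] + side * offset
  start0 <- center - len %/% 2L
  # background fragments
  bgChrom <- sample(names(sl), nBg, replace = TRUE, prob = sl / sum(sl))
  bgLen <- sample(50:250, nBg, replace = TRUE)
  bgStart <- as.integer(floor(stats::runif(nBg, 0, sl[bgChrom] - bgLen)))
  chrom <- c(chromOf, bgChrom)
  start0 <- c(start0, bgStart)
  len <- c(len, bgLen)
  start0 <- pmax(start0, 0L)
  end0 <- pmin(start0 + len, sl[chrom])
  keep <- end0 > start0
  fragments <- fragmentsGRanges(chrom[keep], start0[keep], end0[keep], genome)
  # origin annotations: interval covering all sub-sites +/- 100 bp
  lo <- vapply(mode$sites, min, 0L) - 100L
  hi <- vapply(mode$sites, max, 0L) + 100L
  origins <- fragmentsGRanges(layout$chrom, pmax(lo, 0L),
                              pmin(hi, sl[layout$chrom]), genome)
  origins$name <- layout$name
  plantedClass <- ifelse(cfg$landscapeMode == "dispersed", "multiple",
                         ifelse(mode$composite, "multiple", "single"))
  truth <- data.frame(name = layout$name, chrom = layout$chrom,
                      pos = layout$pos,
                      licensingProb = rep(cfg$licensingProb,
                                          length.out = nrow(layout)),
                      plantedClass = plantedClass,
                      stringsAsFactors = FALSE)
  list(fragments = fragments, origins = origins, truth = truth,
       genome = genome)
}

# bin-constant per-bp SignalTrack from a binned GRanges with counts
.binnedToTrack <- function(binned, seqlengths) {
  vals <- lapply(names(seqlengths), function(c1) {
    i <- as.character(GenomicRanges::seqnames(binned)) == c1
    S4Vectors::Rle(values = binned$score[i],
                   lengths = GenomicRanges::width(binned)[i])
  })
  names(vals) <- names(seqlengths)
  new("SignalTrack", values = methods::as(vals, "SimpleRleList"),
      sizeClass = integer(0))
}

#' Generate replication ground truth: timing field, S/G1 and fork tracks
#'
#' Runs the replication simulator on a licensing field to obtain the true
#' mean replication order, then emits: an S-phase depth track whose
#' expected per-bin count is `sseqDepth * (2 - order/max(order))` (cells
#' sampled uniformly through S phase have duplicated early loci more often
#' than late ones), a uniform Poisson G1 depth track, and the per-bin
#' pol-delta (leftward-fork) fraction track derived from the simulated
#' fork directions.
#'
#' @param cfg A [synthConfig()] (supplies `seed` and `sseqDepth`).
#' @param field A [buildLicensingField()] result.
#' @param simCfg A [simConfig()] controlling the simulation.
#' @return A list: `sim` (`simProfile`), `sTrack`, `g1Track`
#'   (bin-constant `SignalTrack`s), `forkTrack` (`GRanges` with pol-delta
#'   fraction `score`), `trueOrder` (`GRanges` mean order).
#' @export
makeReplicationTruth <- function(cfg, field, simCfg = simConfig(nCells = 200)) {
  simCfg$seed <- if (is.null(simCfg$seed)) cfg$seed + 23L else simCfg$seed
  sim <- simulatePopulation(field, simCfg, directions = TRUE)
  set.seed(cfg$seed + 29L)
  v <- sim$bins$score
  vn <- v / max(v)
  sBins <- sim$bins
  sBins$score <- stats::rpois(length(v), cfg$sseqDepth * (2 - vn))
  g1Bins <- sim$bins
  g1Bins$score <- stats::rpois(length(v), cfg$sseqDepth)
  sl <- field$seqlengths
  list(sim = sim,
       sTrack = .binnedToTrack(sBins, sl),
       g1Track = .binnedToTrack(g1Bins, sl),
       forkTrack = sim$deltaFraction,
       trueOrder = sim$bins)
}

#' Generate hybrid-genome SNPs, haplotype genomes and labeled reads
#'
#' Plants SNPs with spacing drawn uniformly from `(2/3..4/3) * snpDensity`
#' bp, substitutes them into the reference to obtain the second haplotype,
#' and draws error-free (or uniformly error-injected) reads from each
#' haplotype with known labels and mismatch counts against both genomes.
#'
#' @param cfg A [synthConfig()].
#' @param genomeBundle A [makeGenome()] result (its `seq` is haplotype A).
#' @return A list: `snps` (SNP table), `hapA`, `hapB` (`DNAStringSet`),
#'   `reads` (data.frame chrom/start/end/mmA/mmB/trueHap), `genome`
#'   (`Seqinfo`).
#' @export
makeHybridReads <- function(cfg, genomeBundle = makeGenome(cfg)) {
  set.seed(cfg$seed + 31L)
  refGenome <- genomeBundle$seq
  sl <- cfg$chromLengths
  snpRows <- list()
  for (c1 in names(sl)) {
    L <- sl[[c1]]
    gaps <- as.integer(round(stats::runif(ceiling(L / (cfg$snpDensity * 2 / 3)),
                                          cfg$snpDensity * 2 / 3,
                                          cfg$snpDensity * 4 / 3)))
    pos <- cumsum(gaps)
    pos <- pos[pos < L - 1]
    ref <- as.character(Biostrings::extractAt(
      refGenome[[c1]], IRanges::IRanges(pos + 1L, width = 1L)))
    ok <- ref %in% c("A", "C", "G", "T")
    pos <- pos[ok]; ref <- ref[ok]
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  "")
    snpRows[[c1]] <- data.frame(chrom = c1, pos = pos, ref = ref, alt = alt,
                                stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, snpRows)
  rownames(snps) <- NULL
  hapB <- buildHybridGenome(refGenome, snps)
  # reads
  n <- cfg$nReads; rl <- cfg$readLength
  trueHap <- sample(c("A", "B"), n, replace = TRUE)
  chrom <- sample(names(sl), n, replace = TRUE, prob = sl / sum(sl))
  start0 <- as.integer(floor(stats::runif(n, 0, sl[chrom] - rl)))
  # SNPs overlapped per read
  nSnp <- integer(n)
  for (c1 in names(sl)) {
    i <- chrom == c1
    sp <- sort(snps$pos[snps$chrom == c1])
    nSnp[i] <- findInterval(start0[i] + rl - 1L, sp) - findInterval(start0[i] - 1L, sp)
  }
  mmOwn <- stats::rbinom(n, rl, cfg$errorRate)
  mmA <- ifelse(trueHap == "A", mmOwn, nSnp + mmOwn)
  mmB <- ifelse(trueHap == "B", mmOwn, nSnp + mmOwn)
  reads <- data.frame(chrom = chrom, start = start0, end = start0 + rl,
                      mmA = mmA, mmB = mmB, trueHap = trueHap,
                      stringsAsFactors = FALSE)
  list(snps = snps, hapA = refGenome, hapB = hapB, reads = reads,
       genome = genomeBundle$genome)
}

#' Write every synthetic input to a directory
#'
#' Emits FASTA, fragment BED, origin BED, SNP TSV, read TSV, binned
#' bedGraphs and a ground-truth JSON, plus a run manifest.
#'
#' @param cfg A [synthConfig()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
writeSyntheticBundle <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gb <- makeGenome(cfg)
  lib <- makeChecLibrary(cfg)
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    fragments = file.path(dir, "fragments.bed"),
    origins = file.path(dir, "origins.bed"),
    truth = file.path(dir, "ground_truth.json"))
  Biostrings::writeXStringSet(gb$seq, paths$fasta)
  writeFragments(lib$fragments, paths$fragments)
  utils::write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(lib$origins)),
               start = GenomicRanges::start(lib$origins) - 1L,
               end = GenomicRanges::end(lib$origins),
               name = lib$origins$name),
    paths$origins, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  jsonlite::write_json(lib$truth, paths$truth, auto_unbox = TRUE, digits = NA)
  runManifest(file.path(dir, "manifest.json"), stage = "synth",
              config = unclass(cfg), seed = cfg$seed,
              inputs = character(0))
  invisible(paths)
}
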