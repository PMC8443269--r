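# seeded ground-truth generator

smallCfg <- function(...) {
  args <- list(seed = 41L, chromLengths = c(s1 = 200000L), nOrigins = 20L,
               fragmentCount = 20000L, nReads = 4000L)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthConfig, args)
}

test_that("every generator output is bit-identical under the same seed", {
  cfg <- smallCfg()
  g1 <- makeGenome(cfg); g2 <- makeGenome(cfg)
  expect_identical(as.character(g1$seq), as.character(g2$seq))
  l1 <- makeChecLibrary(cfg); l2 <- makeChecLibrary(cfg)
  expect_identical(GenomicRanges::start(l1$fragments),
                   GenomicRanges::start(l2$fragments))
  expect_identical(GenomicRanges::width(l1$fragments),
                   GenomicRanges::width(l2$fragments))
  h1 <- makeHybridReads(cfg, g1); h2 <- makeHybridReads(cfg, g2)
  expect_identical(h1$snps, h2$snps)
  expect_identical(h1$reads, h2$reads)
  # a different seed changes the data
  lX <- makeChecLibrary(smallCfg(atBias = 1)); lX2 <- makeChecLibrary(
    synthConfig(seed = 42, chromLengths = c(s1 = 200000L), nOrigins = 20L,
                fragmentCount = 20000L))
  expect_false(identical(GenomicRanges::start(lX$fragments),
                         GenomicRanges::start(lX2$fragments)))
})

test_that("genome carries AT-rich islands at origins over the set background", {
  cfg <- smallCfg()
  g <- makeGenome(cfg)
  atFrac <- function(seqStr, lo1, hi1) {
    sub <- Biostrings::subseq(seqStr, lo1, hi1)
    sum(Biostrings::letterFrequency(sub, c("A", "T"))) / (hi1 - lo1 + 1)
  }
  island <- vapply(g$origins$pos, function(p)
    atFrac(g$seq[["s1"]], p - 99, p + 100), 0)
  expect_true(all(island > 0.8))
  whole <- atFrac(g$seq[["s1"]], 1, 200000)
  expect_lt(whole, 0.66)
  expect_gt(whole, 0.58)
  # atBias = 0 disables the islands
  g0 <- makeGenome(smallCfg(atBias = 0))
  island0 <- vapply(g0$origins$pos, function(p)
    atFrac(g0$seq[["s1"]], p - 99, p + 100), 0)
  expect_lt(mean(island0), 0.75)
})

test_that("fragment library is bimodal: ~60 bp cores and 150-200 bp nucleosomes", {
  cfg <- smallCfg()
  lib <- makeChecLibrary(cfg)
  w <- GenomicRanges::width(lib$fragments)
  expect_equal(length(w), cfg$fragmentCount)
  coreMode <- as.integer(names(which.max(table(w[w <= 120]))))
  expect_true(coreMode >= 50 && coreMode <= 70)
  nucFrac <- mean(w >= 150 & w <= 200)
  expect_gt(nucFrac, 0.5)                       # ~2/3 of origin fragments
  expect_gt(mean(w >= 40 & w <= 90), 0.25)      # ~1/3 cores
  # truth table and annotations line up
  expect_equal(nrow(lib$truth), 20)
  expect_true(all(lib$truth$plantedClass == "single"))
  expect_equal(GenomicRanges::width(lib$origins), rep(200L, 20))
  # composites are planted as two-site multiples
  libC <- makeChecLibrary(smallCfg(compositeFraction = 1))
  expect_true(all(libC$truth$plantedClass == "multiple"))
  expect_true(all(GenomicRanges::width(libC$origins) == 400L))
  # dispersed mode scatters a large background share
  libD <- makeChecLibrary(smallCfg(landscapeMode = "dispersed"))
  expect_true(all(libD$truth$plantedClass == "multiple"))
})

test_that("hybrid reads overlap SNPs and carry truthful mismatch labels", {
  cfg <- smallCfg()
  hr <- makeHybridReads(cfg)
  # SNP spacing near the configured density
  gaps <- diff(hr$snps$pos)
  expect_true(abs(mean(gaps) - cfg$snpDensity) < 10)
  # hapB differs from hapA at exactly the SNP positions
  diffs <- which(strsplit(as.character(hr$hapA[["s1"]]), "")[[1]] !=
                   strsplit(as.character(hr$hapB[["s1"]]), "")[[1]])
  expect_equal(diffs - 1L, sort(hr$snps$pos))
  # with 150 bp reads and ~75 bp spacing, nearly all reads are diagnostic
  informative <- pmax(hr$reads$mmA, hr$reads$mmB) > 0
  expect_gt(mean(informative), 0.85)
  # error-free reads match their own haplotype perfectly
  own <- ifelse(hr$reads$trueHap == "A", hr$reads$mmA, hr$reads$mmB)
  expect_true(all(own == 0))
  # the read filter recovers the true labels for every assigned read
  ad <- filterDiagnosticReads(hr$reads, hr$snps, hr$genome)
  assigned <- ad$assigned != "dropped"
  expect_gt(mean(assigned), 0.85)
  expect_true(all(as.character(ad$assigned[assigned]) ==
                    hr$reads$trueHap[assigned]))
})

test_that("replication truth couples S/G1 depth to simulated order", {
  cfg <- smallCfg()
  lib <- makeChecLibrary(cfg)
  field <- suppressWarnings(buildLicensingField(coverageTrack(lib$fragments)))
  rt <- makeReplicationTruth(cfg, field,
                             simConfig(nInitial = 10, nCells = 60))
  v <- rt$trueOrder$score
  sBin <- binTrack(rt$sTrack, 1000)$score / 1000
  g1Bin <- binTrack(rt$g1Track, 1000)$score / 1000
  expect_equal(mean(g1Bin), cfg$sseqDepth, tolerance = 0.05)
  early <- v <= quantile(v, 0.1)
  late <- v >= quantile(v, 0.9)
  expect_gt(mean(sBin[early]), mean(sBin[late]) * 1.3)
  d <- rt$forkTrack$score
  expect_true(all(d[!is.na(d)] >= 0 & d[!is.na(d)] <= 1))
  # rerunning with the same config reproduces the same truth
  rt2 <- makeReplicationTruth(cfg, field,
                              simConfig(nInitial = 10, nCells = 60))
  expect_identical(rt$trueOrder$score, rt2$trueOrder$score)
  expect_identical(trackMass(rt$sTrack), trackMass(rt2$sTrack))
})

test_that("synthetic bundle writes readable files with a manifest", {
  cfg <- smallCfg(fragmentCount = 2000L)
  dir <- tempfile("bundle")
  paths <- writeSyntheticBundle(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  gi <- readGenomeIndex(paths$fasta)
  expect_equal(unname(GenomeInfoDb::seqlengths(gi)["s1"]), 200000L)
  fr <- readFragments(paths$fragments, gi)
  expect_length(fr, 2000)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(nrow(truth), 20)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$stage, "synth")
  expect_equal(man$seed, 41)
})
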