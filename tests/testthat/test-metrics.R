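# chromosome-scale binning, smoothing, dispersion, AT profile, correlation

test_that("binning tiles chromosomes, conserves mass and flags partial bins", {
  gi <- fixtureGenome(c(chr1 = 10500L))
  tr <- coverageTrack(fragmentsGRanges("chr1", 0L, 10500L, gi))  # depth 1
  b <- binTrack(tr, 1000)
  expect_length(b, 11)
  expect_equal(b$score[1:10], rep(1000, 10))
  expect_equal(b$score[11], 500)
  expect_equal(b$partial, c(rep(FALSE, 10), TRUE))
  # brute-force oracle on random data
  fr <- randomFragments(120, gi, seed = 13)
  trR <- coverageTrack(fr)
  bR <- binTrack(trR, 1000)
  v <- trackWindow(trR, "chr1", 0, 10500)
  brute <- tapply(v, rep(1:11, times = c(rep(1000, 10), 500)), sum)
  expect_equal(bR$score, unname(as.numeric(brute)))
  expect_equal(sum(bR$score), trackMass(trR))
})

test_that("sliding-window smoothing averages with shrinking edges", {
  gi <- fixtureGenome(c(chr1 = 30000L))
  tr <- coverageTrack(fragmentsGRanges("chr1", 0L, 30000L, gi))
  b <- binTrack(tr, 1000)
  expect_equal(smoothBins(b, 15)$score, b$score)           # constant unchanged
  # unit impulse
  b$score <- rep(0, 30); b$score[15] <- 1
  sm <- smoothBins(b, 15)
  expect_equal(sm$score[8:22], rep(1 / 15, 15))
  expect_equal(sum(sm$score[1:7]), 0)
  # brute-force convolution oracle (interior bins)
  set.seed(4); b$score <- rpois(30, 10)
  sm2 <- smoothBins(b, 5)
  for (i in 3:28)
    expect_equal(sm2$score[i], mean(b$score[(i - 2):(i + 2)]))
  # edge uses the bins available
  expect_equal(sm2$score[1], mean(b$score[1:3]))
  expect_error(smoothBins(b, 4), "odd")
  expect_error(smoothBins(b, 31), "larger")
})

test_that("dispersion ratio and cumulative curve match hand computation", {
  mkBins <- function(v) GenomicRanges::GRanges(
    "z", IRanges::IRanges(seq(1, by = 10, length.out = length(v)), width = 10),
    score = v)
  d <- dispersionReport(mkBins(1:100))
  expect_equal(d$ratio, 98 / 3)                        # medians {96..100},{1..5}
  expect_equal(d$topMedian, 98)
  expect_equal(d$bottomMedian, 3)
  # uniform bins: ratio 1; 80% of signal needs 80% of bins
  u <- dispersionReport(mkBins(rep(7, 100)))
  expect_equal(u$ratio, 1)
  expect_equal(binsForSignalFraction(u, 0.8), 0.8)
  # one bin holds everything: infinite-flagged; 80% at 1% of bins
  s <- dispersionReport(mkBins(c(1000, rep(0, 99))))
  expect_true(s$infinite)
  expect_equal(binsForSignalFraction(s, 0.8), 0.01)
  # scale invariance and monotone curve
  d2 <- dispersionReport(mkBins((1:100) * 13))
  expect_equal(d2$ratio, d$ratio)
  expect_true(all(diff(d$curve$signalFraction) >= 0))
  expect_equal(d$curve$signalFraction[100], 1)
})

test_that("fraction-of-median normalizes the genome-wide median to 1", {
  mkBins <- function(v) GenomicRanges::GRanges(
    "z", IRanges::IRanges(seq(1, by = 10, length.out = length(v)), width = 10),
    score = v)
  expect_equal(fractionOfMedian(mkBins(c(1, 2, 3)))$score, c(0.5, 1, 1.5))
  set.seed(8)
  fm <- fractionOfMedian(mkBins(rgamma(101, 2)))
  expect_equal(median(fm$score), 1)
  expect_error(fractionOfMedian(mkBins(rep(0, 10))), "median")
})

test_that("AT-content profile averages signal per AT-count class", {
  # alternating 30-mers: all-AT then all-GC, signal only on AT bins
  atBlock <- paste(rep("AT", 15), collapse = "")
  gcBlock <- paste(rep("GC", 15), collapse = "")
  seqStr <- paste(rep(c(atBlock, gcBlock), 10), collapse = "")
  dss <- Biostrings::DNAStringSet(seqStr); names(dss) <- "c1"
  gi <- genomeIndex("c1", nchar(seqStr))
  starts <- seq(0L, by = 60L, length.out = 10)             # AT bins only
  fr <- fragmentsGRanges(rep("c1", 10), starts, starts + 30L, gi)
  prof <- atContentProfile(dss, coverageTrack(fr))
  expect_equal(prof$meanSignal[prof$atCount == 30], 30)
  expect_equal(prof$meanSignal[prof$atCount == 0], 0)
  expect_true(all(is.na(prof$meanSignal[prof$atCount %in% 1:29])))

  # brute-force oracle on a random genome/track
  set.seed(17)
  L <- 3000L
  bases <- sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.29, 0.01))
  dss2 <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(dss2) <- "c2"
  gi2 <- genomeIndex("c2", L)
  fr2 <- randomFragments(60, gi2, seed = 18, lenRange = c(20L, 80L))
  tr2 <- coverageTrack(fr2)
  prof2 <- atContentProfile(dss2, tr2)
  v <- trackWindow(tr2, "c2", 0, L)
  for (b in seq_len(L %/% 30)) {
    idx <- ((b - 1) * 30 + 1):(b * 30)
    if (any(bases[idx] == "N")) next
    k <- sum(bases[idx] %in% c("A", "T"))
    expect_true(prof2$nBins[prof2$atCount == k] >= 1)
  }
  # recompute class means independently
  binAT <- sapply(seq_len(L %/% 30), function(b) {
    idx <- ((b - 1) * 30 + 1):(b * 30)
    if (any(bases[idx] == "N")) NA_integer_ else sum(bases[idx] %in% c("A", "T"))
  })
  binSig <- sapply(seq_len(L %/% 30), function(b)
    sum(v[((b - 1) * 30 + 1):(b * 30)]))
  for (k in 0:30) {
    sel <- which(!is.na(binAT) & binAT == k)
    if (length(sel))
      expect_equal(prof2$meanSignal[prof2$atCount == k], mean(binSig[sel]))
    else
      expect_true(is.na(prof2$meanSignal[prof2$atCount == k]))
  }
})

test_that("track correlation matches the textbook formula and flags degeneracy", {
  mkBins <- function(v) GenomicRanges::GRanges(
    "z", IRanges::IRanges(seq(1, by = 10, length.out = length(v)), width = 10),
    score = v)
  set.seed(21)
  x <- rnorm(50); y <- 2 * x + rnorm(50)
  a <- mkBins(x); b <- mkBins(y)
  expect_equal(trackCorrelation(a, a)$r, 1)
  expect_equal(trackCorrelation(a, mkBins(-x + 3))$r, -1)
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(trackCorrelation(a, b)$r, rHand)
  expect_equal(trackCorrelation(a, mkBins(rep(1, 50)))$flag, "zero variance")
  # exclusion list drops bins
  excl <- GenomicRanges::GRanges("z", IRanges::IRanges(1, 100))
  expect_equal(trackCorrelation(a, b, exclude = excl)$n, 40)
})

test_that("origin scatter pairs values and errors on mismatched sets", {
  v <- c(o1 = 1, o2 = 2, o3 = 3)
  r <- c(o3 = 6, o1 = 2, o2 = 4)
  sc <- originScatter(v, r)
  expect_equal(sc$r, 1)
  expect_equal(sc$table$reference, c(2, 4, 6))
  expect_error(originScatter(v, c(o1 = 1, oX = 2)), "oX")
})
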