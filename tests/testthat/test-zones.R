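# initiation/termination zone calling from fork-direction tracks

test_that("zone centers interpolate threshold crossings with correct kinds", {
  # delta fraction 0.8 -> 0.2 between bin centers 10000 and 11000: downward
  # crossing (initiation) exactly halfway
  tr <- forkPoints("c1", c(10000, 11000, 30000, 31000, 50000, 51000),
                   c(0.8, 0.2, 0.2, 0.8, 0.9, 0.3))
  z <- callZones(tr)
  expect_length(z, 3)
  expect_equal(GenomicRanges::start(z) - 1L, c(10500L, 30500L, 50667L))
  expect_equal(z$kind, c("initiation", "termination", "initiation"))
  # kinds alternate along a chromosome by construction of crossings
  expect_true(all(z$kind[-1] != z$kind[-length(z)]))
})

test_that("zones closer than minSeparation to an opposite kind are removed", {
  tr <- forkPoints("c1", c(10000, 11000, 12000, 13000),
                   c(0.8, 0.2, 0.2, 0.8))
  # crossings at 10500 (init) and 12500 (term), 2000 bp apart: both dropped
  expect_length(callZones(tr), 0)
  # same crossings kept when the filter is disabled
  z <- callZones(tr, zoneConfig(minSeparation = 0))
  expect_length(z, 2)
  # symmetric removal: filterZonePairs drops both members of a close pair
  zz <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(c(1000, 3000, 50000), width = 1),
    kind = c("initiation", "termination", "initiation"))
  kept <- filterZonePairs(zz, 5000)
  expect_equal(GenomicRanges::start(kept), 50000)
})

test_that("constant or NA-laden tracks are handled", {
  expect_warning(z <- callZones(forkPoints("c1", c(1000, 2000, 3000),
                                           c(0.7, 0.7, 0.7))),
                 "no threshold crossings")
  expect_length(z, 0)
  # NA bins are skipped, not treated as crossings
  tr <- forkPoints("c1", c(10000, 11000, 12000), c(0.8, NA, 0.2))
  z2 <- callZones(tr)
  expect_length(z2, 1)
  expect_equal(GenomicRanges::start(z2) - 1L, 11000L)  # midway 10000..12000
})

test_that("many-crossing track yields alternating, well-separated zones", {
  x <- seq(50, 99950, by = 100)
  d <- 0.5 + 0.45 * sin(2 * pi * x / 20000)
  tr <- GenomicRanges::GRanges("c1", IRanges::IRanges(x - 49, width = 100),
                               score = d)
  z <- callZones(tr)
  # crossings at ~10, 20, ..., 90 kb (the boundary crossings at 0 and
  # 100 kb fall outside the binned range)
  expect_equal(length(z), 9)
  for (k in 2:length(z))
    expect_true(z$kind[k] != z$kind[k - 1])
  expect_true(all(diff(GenomicRanges::start(z)) >= 5000))
})

test_that("zone signal comparison computes percent excess and t statistics", {
  bins <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(seq(1, by = 1000, length.out = 10), width = 1000),
    score = c(2, 2, 2, 1, 1, 1, 2, 1, 5, 5))
  mkz <- function(pos0, kind) GenomicRanges::GRanges("c1",
    IRanges::IRanges(pos0 + 1L, width = 1L), kind = kind)
  zones <- c(mkz(c(500, 1500, 2500), "initiation"),
             mkz(c(3500, 4500, 5500), "termination"))
  res <- compareZoneSignal(bins, zones)
  expect_equal(res$summary$mean, c(2, 1))
  expect_equal(res$percentExcess, 100)
  expect_equal(res$t, Inf)                       # zero within-group variance
  expect_equal(res$p, 0)
  expect_equal(res$flag, "constant groups")

  # a bin overlapping both kinds is excluded as ambiguous
  zonesAmb <- c(zones, mkz(8600, "initiation"), mkz(8700, "termination"))
  resA <- compareZoneSignal(bins, zonesAmb)
  expect_equal(resA$summary$n, c(3, 3))

  # control track: per-bin ratio is compared instead
  ctrl <- bins; ctrl$score <- rep(2, 10)
  resC <- compareZoneSignal(bins, zones, control = ctrl)
  expect_equal(resC$summary$mean, c(1, 0.5))
  expect_equal(resC$percentExcess, 100)

  # empty group flagged, no crash
  resE <- compareZoneSignal(bins, zones[zones$kind == "initiation"])
  expect_equal(resE$flag, "a group is empty")
  expect_true(is.na(resE$p))
})

test_that("percent excess CI covers the true excess for noisy groups", {
  set.seed(12)
  bins <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(seq(1, by = 1000, length.out = 400), width = 1000),
    score = c(rnorm(200, 3, 0.3), rnorm(200, 2, 0.3)))
  mkz <- function(pos0, kind) GenomicRanges::GRanges("c1",
    IRanges::IRanges(pos0 + 1L, width = 1L), kind = kind)
  zones <- c(mkz(seq(500, by = 1000, length.out = 200), "initiation"),
             mkz(seq(200500, by = 1000, length.out = 200), "termination"))
  res <- compareZoneSignal(bins, zones)
  expect_true(res$percentExcessCI[1] < 50 && 50 < res$percentExcessCI[2])
  expect_lt(res$p, 1e-10)
})

test_that("peak-adjacent comparison picks flanking bins, honoring edges", {
  bins <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(seq(1, by = 100, length.out = 12), width = 100),
    score = c(3, 1, 1, 9, 9, 1, 1, 1, 1, 6, 1, 1))
  peaks <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(c(1, 301, 901), c(100, 500, 1000)))
  res <- peakAdjacentTest(bins, peaks)
  # peak bins: 1, 4, 5, 10; neighbors: 2 (right of run1), 3, 6, 9, 11
  expect_equal(res$summary$n, c(4, 5))
  expect_equal(res$summary$mean[1], mean(c(3, 9, 9, 6)))
  expect_equal(res$summary$mean[2], 1)
  # uniform signal: zero excess
  bu <- bins; bu$score <- rep(4, 12)
  expect_equal(peakAdjacentTest(bu, peaks)$percentExcess, 0)
})

test_that("fork-track reading supports both dialects; zones round-trip", {
  f <- tempfile()
  writeLines(c("c1\t0\t0.8", "c1\t1000\t0.2", "c1\t2000\t0.4"), f)
  tr <- readForkTrack(f)
  expect_equal(GenomicRanges::width(tr), rep(1000, 3))
  expect_equal(tr$score, c(0.8, 0.2, 0.4))
  f2 <- tempfile()
  writeLines(c("c1\t0\t500\t0.9", "c1\t500\t1000\t0.1"), f2)
  tr2 <- readForkTrack(f2)
  expect_equal(GenomicRanges::width(tr2), c(500, 500))
  z <- callZones(forkPoints("c1", c(10000, 11000), c(0.8, 0.2)))
  fz <- tempfile(fileext = ".bed")
  writeZones(z, fz)
  tab <- read.table(fz)
  expect_equal(tab$V2, 10500)
  expect_equal(tab$V4, "initiation")
})
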