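#' Replication simulator configuration
#'
#' The stochastic model has three parameters: the bin size into which MCM
#' signal is grouped to form the activation probability distribution, the
#' number of MCM complexes activated at the start of S phase, and the
#' distance forks travel before the next activation batch (one new
#' activation per converged fork pair) is drawn ("recycling").
#'
#' @param binSize Licensing bin size in bp (default 1000).
#' @param nInitial Origins activated at S-phase start (default 300).
#' @param recycleDistance bp of fork travel per activation round (default
#'   5000); `0` or `Inf` disables recycling entirely.
#' @param nCells Number of simulated cells (default 1000).
#' @param seed Optional RNG seed recorded with every run.
#' @param convergencePerFork Count each converged fork (rather than each
#'   converged pair) as one new activation (default `FALSE`).
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(binSize = 1000L, nInitial = 300L,
                      recycleDistance = 5000L, nCells = 1000L,
                      seed = NULL, convergencePerFork = FALSE) {
  stopifnot(binSize >= 1, nInitial >= 1, nCells >= 1)
  structure(list(binSize = as.integer(binSize), nInitial = as.integer(nInitial),
                 recycleDistance = as.numeric(recycleDistance),
                 nCells = as.integer(nCells), seed = seed,
                 convergencePerFork = convergencePerFork),
            class = "simConfig")
}

#' Build the licensing field (per-bin activation probabilities)
#'
#' Bins the all-size MCM signal at the configured bin size and normalizes
#' bin masses to probabilities. The central base pair of each bin is where
#' an activated origin's forks start.
#'
#' @param track All-size `SignalTrack` of MCM signal.
#' @param cfg A [simConfig()] (its `binSize` is used).
#' @return A list of class `licensingField`: per-bin `chrom`, 0-based bin
#'   `center0`, `prob` (sums to 1), plus `binSize` and `seqlengths`.
#' @export
buildLicensingField <- function(track, cfg = simConfig()) {
  binned <- binTrack(track, cfg$binSize)
  s <- binned$score
  if (sum(s) <= 0) stop("licensing track is all zero")
  chrom <- as.character(GenomicRanges::seqnames(binned))
  start0 <- GenomicRanges::start(binned) - 1L
  width <- GenomicRanges::width(binned)
  sl <- lengths(trackValues(track))
  perChrom <- tapply(s, chrom, sum)
  zero <- names(perChrom)[perChrom == 0]
  if (length(zero))
    warning("chromosome(s) with no licensing mass cannot replicate: ",
            paste(zero, collapse = ", "))
  structure(list(chrom = chrom, center0 = start0 + width %/% 2L,
                 prob = s / sum(s), binSize = cfg$binSize,
                 seqlengths = sl), class = "licensingField")
}

# discrete sums ------------------------------------------------------------

# sum of integers a..b (0 when b < a); vectorized
.sumTo <- function(a, b) ifelse(b < a, 0, (a + b) * (b - a + 1) / 2)

# sum over integer x in [a, b] of |x - c|; vectorized over equal-length args
.sumAbs <- function(c0, a, b) {
  bl <- pmin(b, c0)
  left <- ifelse(bl >= a, (bl - a + 1) * c0 - .sumTo(a, bl), 0)
  ar <- pmax(a, c0 + 1)
  right <- ifelse(b >= ar, .sumTo(ar, b) - (b - ar + 1) * c0, 0)
  left + right
}

# envelope value min_i(t_i + |x - c_i|) at sorted query positions x;
# seeds (c, t) need not be sorted. Returns Inf where no seed exists.
.envelopeAt <- function(x, c0, t0) {
  if (!length(c0)) return(rep(Inf, length(x)))
  o <- order(c0)
  c0 <- c0[o]; t0 <- t0[o]
  leftMin <- cummin(t0 - c0)
  rightMin <- rev(cummin(rev(t0 + c0)))
  jl <- findInterval(x, c0)                      # last seed with c <= x
  jr <- length(c0) - findInterval(-x, rev(-c0))  # first seed with c >= x is jr+1
  lv <- ifelse(jl >= 1, leftMin[pmax(jl, 1)] + x, Inf)
  rv <- ifelse(jr < length(c0), rightMin[pmin(jr + 1, length(c0))] - x, Inf)
  pmin(lv, rv)
}

# territories of sorted seeds on [0, L): integer lo/hi per seed (ties at a
# meeting bp go to the left fork)
.territories <- function(c0, t0, L) {
  o <- order(c0)
  c0 <- c0[o]; t0 <- t0[o]
  n <- length(c0)
  if (n == 1) return(list(c0 = c0, t0 = t0, lo = 0, hi = L - 1))
  B <- (c0[-n] + c0[-1] + t0[-1] - t0[-n]) / 2
  hi <- c(floor(B), L - 1)
  lo <- c(0, floor(B) + 1)
  list(c0 = c0, t0 = t0, lo = lo, hi = hi)
}

#' Simulate replication of one cell
#'
#' Draws `nInitial` distinct licensing bins (weighted by the field), starts
#' bidirectional forks from each bin's central bp (order index 0, +1 per bp
#' of travel), and advances time in rounds of `recycleDistance` bp: at the
#' end of each round the fork pairs that converged during it are counted
#' and that many new origins are drawn, excluding bins already activated
#' and bins whose central bp is already replicated. Forks halt where they
#' meet oncoming forks or chromosome ends; if eligible bins run out the
#' remaining DNA is finished passively. Because forks move 1 bp per order
#' tick, the finished per-bp order field is the lower envelope
#' `min_i(t_i + |x - c_i|)` over activated origins with activation times
#' `t_i` (multiples of `recycleDistance`).
#'
#' @param field A [buildLicensingField()] result.
#' @param cfg A [simConfig()].
#' @return A list of class `cellReplication`: `seeds` (per-chromosome
#'   data.frame of `center0`, `time`), `nActivated`, `nConvergences`,
#'   `nRounds`, `completionTime`.
#' @export
simulateCell <- function(field, cfg = simConfig()) {
  p <- field$prob
  nb <- length(p)
  chrom <- field$chrom
  centers <- field$center0
  sl <- field$seqlengths
  chromNames <- names(sl)
  recycle <- cfg$recycleDistance
  noRecycle <- is.infinite(recycle) || recycle <= 0
  activated <- logical(nb)
  # chromosomes without licensing mass can never replicate (warned at field
  # construction); exclude them from completion accounting
  activeCh <- vapply(chromNames, function(c1) any(p > 0 & chrom == c1), TRUE)

  k0 <- min(cfg$nInitial, sum(p > 0))
  drawn <- sample.int(nb, k0, prob = p)
  activated[drawn] <- TRUE
  seedBin <- drawn
  seedTime <- rep(0, k0)

  # with recycling off, guarantee every chromosome with licensing mass gets
  # at least one origin so the cell terminates
  if (noRecycle) {
    for (ci in seq_along(chromNames)) {
      onCh <- chrom == chromNames[ci]
      if (!any(activated & onCh) && any(p > 0 & onCh)) {
        extra <- which(onCh & p > 0 & !activated)
        pick <- if (length(extra) == 1) extra else
          sample(extra, 1, prob = p[extra])
        activated[pick] <- TRUE
        seedBin <- c(seedBin, pick); seedTime <- c(seedTime, 0)
      }
    }
  }

  nConv <- 0L; r <- 0L
  repeat {
    Tprev <- if (noRecycle) 0 else r * recycle
    Tend <- if (noRecycle) Inf else (r + 1) * recycle
    convRound <- 0L
    completion <- 0
    for (ci in which(activeCh)) {
      inCh <- chrom[seedBin] == chromNames[ci]
      if (!any(inCh)) { completion <- Inf; next }
      c0 <- centers[seedBin[inCh]]; t0 <- seedTime[inCh]
      o <- order(c0); c0 <- c0[o]; t0 <- t0[o]
      L <- sl[[ci]]
      n <- length(c0)
      ends <- c(t0[1] + c0[1], t0[n] + (L - 1 - c0[n]))
      meets <- if (n > 1) (t0[-n] + t0[-1] + c0[-1] - c0[-n]) / 2 else numeric(0)
      completion <- max(completion, ends, meets)
      convRound <- convRound + sum(meets > Tprev & meets <= Tend)
    }
    nConv <- nConv + convRound
    if (noRecycle) break
    if (is.finite(completion) && completion <= Tend) break
    k <- if (cfg$convergencePerFork) 2L * convRound else convRound
    # eligibility: not yet activated, positive mass, central bp unreplicated
    # by the end of this round
    elig <- !activated & p > 0
    if (any(elig)) {
      for (ci in seq_along(chromNames)) {
        onCh <- which(elig & chrom == chromNames[ci])
        if (!length(onCh)) next
        inCh <- chrom[seedBin] == chromNames[ci]
        env <- .envelopeAt(centers[onCh], centers[seedBin[inCh]],
                           seedTime[inCh])
        elig[onCh[env <= Tend]] <- FALSE
      }
    }
    # termination guard: a chromosome with no origins yet cannot finish
    # passively; draw one origin for it even without a convergence credit
    if (k == 0L && is.infinite(completion) && any(elig)) k <- 1L
    k <- min(k, sum(elig))
    if (k > 0L) {
      cand <- which(elig)
      pick <- if (length(cand) == 1) cand else
        sample(cand, k, prob = p[cand])
      activated[pick] <- TRUE
      seedBin <- c(seedBin, pick)
      seedTime <- c(seedTime, rep(Tend, k))
    }
    r <- r + 1L
    if (r > 1e6) stop("simulation failed to terminate")
  }

  seeds <- lapply(chromNames, function(c1) {
    inCh <- chrom[seedBin] == c1
    df <- data.frame(center0 = centers[seedBin[inCh]], time = seedTime[inCh])
    df[order(df$center0), , drop = FALSE]
  })
  names(seeds) <- chromNames
  structure(list(seeds = seeds, nActivated = sum(activated),
                 nConvergences = nConv, nRounds = r + 1L,
                 completionTime = completion, seqlengths = sl),
            class = "cellReplication")
}

#' Per-base-pair replication order field of one simulated cell
#'
#' Materializes `min_i(t_i + |x - c_i|)` for every bp of one chromosome.
#' Intended for small genomes and oracle checks; population profiles use
#' the exact closed-form binned accumulation instead.
#'
#' @param cell A [simulateCell()] result.
#' @param chrom Chromosome name.
#' @return Numeric vector of order indices, one per bp.
#' @export
cellOrderField <- function(cell, chrom) {
  L <- cell$seqlengths[[chrom]]
  sd <- cell$seeds[[chrom]]
  if (nrow(sd) == 0) return(rep(Inf, L))
  idx <- seq.int(0, L - 1)
  f <- rep(Inf, L)
  f[sd$center0 + 1L] <- pmin(f[sd$center0 + 1L], sd$time)
  fwd <- cummin(f - idx) + idx
  bwd <- rev(cummin(rev(f + idx))) - idx
  pmin(fwd, bwd)
}

# exact per-bin sums of the order field and of left/right fork direction
# counts for one chromosome of one cell
.cellBinStats <- function(sd, L, binSize) {
  terr <- .territories(sd$center0, sd$time, L)
  c0 <- terr$c0; t0 <- terr$t0; lo <- terr$lo; hi <- terr$hi
  full <- t0 * (hi - lo + 1) + .sumAbs(c0, lo, hi)
  fullR <- pmax(0, hi - c0)            # bp replicated by rightward forks
  fullL <- pmax(0, c0 - lo)            # leftward
  cumS <- c(0, cumsum(full))
  cumR <- c(0, cumsum(fullR))
  cumL <- c(0, cumsum(fullL))
  edges <- c(seq.int(0, L - 1, by = binSize), L)
  j <- findInterval(edges, lo)          # territory containing each edge
  j[edges == 0] <- 1
  eC <- c0[j]; eT <- t0[j]; eLo <- lo[j]
  partS <- ifelse(edges > eLo,
                  eT * (edges - eLo) + .sumAbs(eC, eLo, edges - 1), 0)
  partR <- ifelse(edges - 1 >= eC + 1, edges - 1 - eC, 0)
  partL <- ifelse(pmin(edges - 1, eC - 1) >= eLo,
                  pmin(edges - 1, eC - 1) - eLo + 1, 0)
  CS <- cumS[j] + partS
  CR <- cumR[j] + partR
  CL <- cumL[j] + partL
  list(binSum = diff(CS), binRight = diff(CR), binLeft = diff(CL),
       width = diff(edges))
}

#' Simulate a cell population and average the replication order
#'
#' Runs [simulateCell()] `nCells` times and returns the per-bin mean
#' replication order (lower = earlier), computed exactly from the per-cell
#' closed-form order field. Optionally accumulates fork-direction
#' fractions (fraction of bp in each bin replicated by leftward-moving
#' forks, i.e. synthesized as lagging Watson strand by pol delta).
#'
#' @param field A [buildLicensingField()] result.
#' @param cfg A [simConfig()]; `cfg$seed`, when set, makes the run
#'   bit-for-bit reproducible.
#' @param directions Also return the per-bin pol-delta (leftward-fork)
#'   fraction (default `FALSE`).
#' @return A list of class `simProfile`: `bins` (`GRanges` with `score` =
#'   mean order), optionally `deltaFraction` (`GRanges` with `score`),
#'   `nCells`, `conserved` (cells in which every bp was replicated exactly
#'   once), `config`.
#' @export
simulatePopulation <- function(field, cfg = simConfig(), directions = FALSE) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sl <- field$seqlengths
  chromNames <- names(sl)
  binSize <- field$binSize
  acc <- lapply(chromNames, function(c1)
    numeric(length(seq.int(0, sl[[c1]] - 1, by = binSize))))
  names(acc) <- chromNames
  accR <- lapply(acc, function(a) a * 0)
  accL <- lapply(acc, function(a) a * 0)
  conserved <- 0L
  for (i in seq_len(cfg$nCells)) {
    cell <- simulateCell(field, cfg)
    ok <- TRUE
    for (c1 in chromNames) {
      sd <- cell$seeds[[c1]]
      if (nrow(sd) == 0) { ok <- FALSE; next }
      st <- .cellBinStats(sd, sl[[c1]], binSize)
      acc[[c1]] <- acc[[c1]] + st$binSum
      if (directions) {
        accR[[c1]] <- accR[[c1]] + st$binRight
        accL[[c1]] <- accL[[c1]] + st$binLeft
      }
    }
    if (ok) conserved <- conserved + 1L
  }
  si <- genomeIndex(chromNames, sl)
  bins <- do.call(c, lapply(chromNames, function(c1) {
    starts <- seq.int(1, sl[[c1]], by = binSize)
    width <- pmin(binSize, sl[[c1]] - starts + 1L)
    GenomicRanges::GRanges(c1, IRanges::IRanges(starts, width = width),
                           score = acc[[c1]] / (cfg$nCells * width),
                           seqinfo = si)
  }))
  res <- list(bins = bins, nCells = cfg$nCells, conserved = conserved,
              config = cfg)
  if (directions) {
    df <- bins
    tot <- unlist(lapply(chromNames, function(c1) accR[[c1]] + accL[[c1]]))
    lf <- unlist(lapply(chromNames, function(c1) accL[[c1]]))
    df$score <- ifelse(tot > 0, lf / tot, NA_real_)
    res$deltaFraction <- df
  }
  structure(res, class = "simProfile")
}

#' Correlate a simulated profile with an S/G1 replication track
#'
#' The mean replication order is negated before correlating, so a positive
#' r means agreement (earlier simulated replication where the S/G1 ratio is
#' high).
#'
#' @param sim A [simulatePopulation()] result (or its `bins`).
#' @param sseq `GRanges` of bins with `score` (S/G1 ratio), same binning.
#' @return A list: `global` r, `perChromosome` named vector, `flag`.
#' @export
profileVsSseq <- function(sim, sseq) {
  bins <- if (is(sim, "GRanges")) sim else sim$bins
  if (length(bins) != length(sseq)) stop("binning differs")
  x <- -bins$score; y <- sseq$score
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(global = NA_real_, perChromosome = NULL,
                flag = "zero variance"))
  ch <- as.character(GenomicRanges::seqnames(bins))
  per <- vapply(unique(ch), function(c1) {
    i <- ch == c1
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) NA_real_ else
      stats::cor(x[i], y[i])
  }, 0)
  list(global = stats::cor(x, y), perChromosome = per, flag = NA_character_)
}

#' Robustness sweep over simulator parameters
#'
#' Simulates the population under each configuration in `grid` and reports
#' the Pearson correlation of every profile with the first (reference)
#' profile and between all pairs.
#'
#' @param field A [buildLicensingField()] result.
#' @param grid A list of [simConfig()] objects; the first is the reference.
#' @return A list: `profiles` (list of `simProfile`), `vsReference`
#'   (numeric), `pairwise` (matrix).
#' @export
robustnessSweep <- function(field, grid) {
  profiles <- lapply(grid, function(cfg) simulatePopulation(field, cfg))
  scores <- lapply(profiles, function(p) p$bins$score)
  n <- length(scores)
  pw <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i < j) pw[i, j] <- pw[j, i] <- stats::cor(scores[[i]], scores[[j]])
  list(profiles = profiles, vsReference = pw[1, ], pairwise = pw)
}
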