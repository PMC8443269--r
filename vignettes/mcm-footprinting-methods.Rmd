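---
title: "MCM footprinting, licensing dispersion and stochastic replication timing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MCM footprinting, licensing dispersion and stochastic replication timing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MCMfootprints)
```

This vignette documents the models, default parameters, numerical
conventions and known limitations of the package. It is the reference for
*why* each default is what it is; function-level details live in the help
pages.

# Data model and coordinate conventions

ChEC (chromatin endogenous cleavage) libraries are paired-end fragment
tables: `chrom`, `start`, `end` in 0-based half-open coordinates (BED
convention). `readFragments()` validates every record against a genome
index (`Seqinfo`) and converts to 1-based closed `GRanges`; all file
interfaces stay 0-based half-open, all in-memory `GRanges` follow the
Bioconductor convention. Coverage is held as `RleList` inside the
`SignalTrack` S4 class, which also records the fragment-size class it was
built from.

Fragment size is the biological readout: one MCM2-7 double hexamer
protects ~60 bp, so the **51–100 bp** class is treated as the MCM
footprint channel, and **151–200 bp** as the nucleosomal channel. These
bands are parameters (`sizeClass=`) everywhere, with those defaults.

# Origin-centered heat matrices

`heatMatrix()` accumulates, for a window of `halfWindow = 1500` bp on
each side of an origin midpoint and fragment lengths `1..maxFragLen`
(`maxFragLen = 500`), the per-base-pair depth of fragments of each exact
length: a 500 × 3001 matrix. The invariant used as a correctness oracle
throughout the tests is that summing matrix rows over a size band equals
the size-class coverage track restricted to the window, exactly.
`renderHeatmap()` writes a PNG with an optional intensity cap and records
the cap and the uncapped maximum in a `.meta.tsv` sidecar, so rendered
images remain auditable.

# Single vs multiple footprint classification

For each annotated origin, in the 51–100 bp track:

1. **Peak**: the maximum depth position within ±`flank` (800 bp) of the
   origin midpoint; ties resolve to the *leftmost* position so the call
   is deterministic.
2. **Noise cut**: positions with depth below `noiseFrac` (10%) of the
   peak height are ignored.
3. **Single fraction**: supra-noise signal within ±`peakHalfwidth`
   (60 bp) of the peak divided by supra-noise signal in the whole
   window. The statistic is scale-invariant (doubling the library leaves
   it unchanged).
4. **Class**: `single` iff the fraction is at least
   `singleThreshold = 0.80` (inclusive boundary — an exactly-0.80 origin
   is a single).

Origin **abundance** is the all-size signal summed over midpoint ±800 bp
(1601 bp). `compareFootprintClasses()` reports per-class means and a
two-tailed unpaired t test (Welch by default; `varEqual = TRUE` for the
pooled form). Degenerate inputs (a constant group, an empty class) return
flagged `NA`/limit values instead of erroring, because genome-wide scans
routinely hit them.

# Chromosome-scale dispersion

`binTrack()` sums coverage into fixed-width bins (partial terminal bins
are flagged); `smoothBins()` is a centered moving average with shrinking
windows at chromosome ends; the overview traces and the simulator-vs-S/G1
comparisons use **15-bin** smoothing.

`dispersionReport()` ranks bins by signal (ties broken by genomic
position), takes the top and bottom `q = 5%` (`k = max(1, round(qN))`
bins per tail) and reports the ratio of tail medians, plus the cumulative
signal-vs-bins curve; `binsForSignalFraction()` reads off, e.g., the bin
fraction holding 80% of the signal. The hand-checkable fixture `1..100`
gives `98/3 = 32.67`. A zero bottom median is reported as `ratio = Inf`
with `infinite = TRUE` rather than an error.

`atContentProfile()` bins the genome into 30 bp windows, counts A/T per
window (windows containing any non-ACGT base are ineligible) and averages
signal per AT-count class; empty classes are `NA`, not 0.

# Initiation/termination zone calling

The fork-direction input is the per-bin fraction of Watson-strand
synthesis by polymerase delta (Pu-seq convention), equivalently the
fraction of leftward-moving forks. `callZones()` places a zone at every
crossing of `majorityThreshold = 0.5`, linearly interpolated between the
two flanking bin centers; downward crossings (delta-majority on the left)
are **initiation** zones, upward crossings **termination** zones. Zones
closer than `minSeparation = 5000` bp to the nearest opposite-kind zone
are removed. Marking is symmetric — both members of a close pair get
marked — so removing "the pair" and removing "each focal zone" are the
same operation; the single implementation covers both readings.

`compareZoneSignal()` compares binned signal (1 kb default) between bins
overlapping initiation vs termination zones, with optional division by a
control track (e.g. sonicated G1 DNA), reporting the percent excess of
the initiation mean with a 95% confidence interval derived from the
Welch t interval.

# The replication simulator

The model has three parameters: `binSize = 1000` (licensing bins),
`nInitial = 300` (origins activated at S-phase entry) and
`recycleDistance = 5000` bp (fork travel per activation round).
`buildLicensingField()` normalizes binned MCM signal to per-bin
activation probabilities; activated bins fire bidirectional forks from
the bin's central bp.

**Numerical formulation.** Forks move 1 bp per order tick, so the
finished per-bp replication-order field of a cell is the lower envelope
$\min_i \left( t_i + |x - c_i| \right)$ over activated origins with
activation times $t_i$ (multiples of `recycleDistance`). The simulator
therefore never materializes per-bp arrays during population runs: a
cell is just its seed list $(c_i, t_i)$. Adjacent-seed territories have
closed-form boundaries $B = (c_i + c_j + t_j - t_i)/2$ (ties at a
meeting bp go to the left fork), per-bin sums of the order field follow
from arithmetic-series identities evaluated at bin edges, and per-bin
leftward/rightward fork counts come from the same territory bookkeeping
— all exact, verified against brute-force per-bp materialization in the
tests. `cellOrderField()` retains the per-bp form for small genomes and
oracle checks.

**Rounds.** At the end of each `recycleDistance`-long round, converged
fork pairs during that round are counted and that many new origins are
drawn (without replacement, weighted by the field) among bins that are
unactivated and whose central bp is not yet replicated by the end of the
round. Eligibility uses the same envelope evaluated at candidate
centers. Two termination guards exist: with recycling disabled, each
chromosome with licensing mass receives at least one time-0 origin; with
recycling on, a chromosome that has no origin yet and no convergence
credit pending draws one eligible origin so the cell always finishes.
Chromosomes with zero licensing mass are excluded from completion
accounting and flagged with a warning at field construction — they can
never replicate in this model.

`simulatePopulation()` averages per-bin order over `nCells = 1000` cells
(`seed` makes runs bit-reproducible), verifies per-cell mass conservation
(every bp replicated exactly once, reported as `conserved`), and can
accumulate the per-bin leftward-fork fraction, which doubles as a
synthetic polymerase-usage track. `profileVsSseq()` negates mean order
before correlating so positive r means agreement with an S/G1 ratio
track. `robustnessSweep()` re-simulates under a configuration grid and
reports profile correlations against the first (reference) entry —
the model's predictions are expected to be robust to halving `nInitial`
and to disabling recycling entirely.

# Allele-specific (hybrid-genome) analysis

`buildHybridGenome()` substitutes a SNP table (0-based positions,
single-base ref/alt) into the reference to form the second haplotype,
checking every reference base first. `filterDiagnosticReads()` assigns a
read to a haplotype iff it overlaps at least one SNP *and* has zero
mismatches against exactly one haplotype genome; everything else is
dropped. `sseqProfile()` forms per-bin S/G1 ratios normalized to median
1. `fluctuationRatio()` computes, per chromosome, the unscaled median
absolute deviation of each haplotype's profile and their A/B ratio: a
homolog whose replication-timing fluctuations are compressed (the
inactive X being the motivating case) drives the ratio away from 1 and
is reported as the outlier chromosome.

# Synthetic ground-truth generator

Every generator function derives its RNG stream from `synthConfig(seed)`
plus a fixed per-function offset, so each output is individually
reproducible and mutually consistent. Defaults emulate the study
conditions at desk scale: 2 × 1 Mb chromosomes, 200 origins on a
jittered grid, 200,000 fragments, licensing probability 0.9, protected
cores N(60, 4) clamped to 40–90 bp (1/3 of origin fragments), flanking
nucleosomal fragments 150–200 bp offset 30–50 bp beyond the core edge
(2/3), 5% uniform background, genome AT fraction 0.62 with 200 bp
90%-AT islands planted at origins, SNPs every ~75 bp, 150 bp error-free
hybrid reads, and S/G1 tracks at `sseqDepth = 500` expected reads per
1 kb bin.

Two design points deserve emphasis:

* **Dispersed landscapes.** Spreading each origin's sites over
  500–1500 bp is invisible to 5 kb dispersion bins, so `dispersed` mode
  additionally scatters at least 40% of fragments genome-wide,
  emulating the substantial inter-origin licensing that distinguishes
  fission-yeast/human landscapes from budding yeast. The
  focused-vs-dispersed contrast in dispersion ratio and
  bins-for-80%-signal is a property of this regime.
* **S/G1 depth.** An S-phase bin's expected depth is
  `sseqDepth * (2 - order/max(order))` — cells sampled uniformly through
  S phase have duplicated early loci more often. At depth 500 the
  per-bin Poisson noise is still visible; comparisons against simulated
  order use the standard 15-bin smoothing, since raw counting noise is
  not replication signal.

`makeReplicationTruth()` ties the generator to the simulator: the same
simulated population provides the true order field, the S/G1 tracks and
the fork-direction track, so zone calls and timing correlations can be
scored against a planted truth. `writeSyntheticBundle()` materializes
everything (FASTA, BEDs, TSVs, ground-truth JSON) with a `runManifest()`
JSON recording parameters, seed and input checksums.

# Problem sizes and runtime

The acceptance-scale workloads used in the test suite: classifier on
2 Mb / 200 origins / 200,000 fragments (seconds); 1000-cell population
simulation on a 12 Mb, 4-chromosome genome at 1 kb bins (tens of
seconds, exact conservation in 1000/1000 cells); robustness sweeps of
3 × 500–1000 cells on 2 Mb landscapes (under a minute each); zone
recall/precision on simulator-generated fork tracks from 50 planted
origins (seconds).

# Limitations

* The simulator is deliberately minimal: constant fork speed, no
  stochastic firing-time jitter within a round, no fork stalling or
  dormant-origin passivation beyond what the envelope implies; time is
  measured in bp of travel, not minutes.
* The synthetic ChEC library plants clean size classes; real libraries
  carry MNase digestion gradients and mappability artifacts the
  generator does not model.
* Hybrid reads carry mismatch *counts*, not alignments; the diagnostic
  filter therefore models the decision rule, not an aligner.
* The classifier assumes one annotated interval per origin; overlapping
  annotations should be merged or excluded (`exclude=`) upstream.
* Published-data reproduction requires external downloads and is out of
  scope for the offline test suite; the end-to-end acceptance block
  composes the same pipeline stages on generated files instead.
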