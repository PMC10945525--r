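---
title: "Methods: contact-range, domain-boundary and matS/Ter analysis with terscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-range, domain-boundary and matS/Ter analysis with terscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

terscope implements the computational side of a bacterial
chromosome-conformation study: how the MatP/matS system confines the
activity of the MukBEF condensin to outside the replication-terminus
(Ter) macrodomain of *E. coli*. The package covers five analyses —
contact-map construction and balancing, the per-locus "range of cis
contacts" statistic, directional-index (DI) domain-boundary calling,
ChIP-seq enrichment and peak calling, and matS/Ter comparative genomics
— plus a synthetic-data module that generates inputs with the
statistical structure each analysis assumes, so that the whole pipeline
is testable without sequencing data. Wet-lab steps and read alignment
are out of scope: the pipeline consumes mapped pairs, coverage tracks
and genome sequences.

# Contact maps

Read pairs are assigned to restriction fragments of the digest (HpaII,
`C^CGG`, by default). Pairs in one fragment (self-circularization) and
pairs in adjacent fragments reading toward each other (uncut co-linear
molecules) carry no contact information and are discarded; no
religation-distance heuristic beyond adjacency is applied, because only
these two event classes are structurally non-informative. Valid events
are binned at 5 kb (the working resolution of all downstream analyses;
the ceiling rule gives the last bin short measure) into a symmetric
count matrix over the circular chromosome.

Balancing uses sequential component normalization (SCN): alternating L1
row and column normalization with symmetrization (averaging with the
transpose) after each sweep, until the coefficient of variation of the
unmasked row sums falls below `tol`. The method itself fixes no
constants, so the package chooses `tol = 1e-6`, `max_iter = 200`, and a
low-coverage mask of bins whose raw marginal is below 10% of the median
marginal (plus all-zero bins); all three are exposed arguments.
Convergence is linear and typically reached in well under 50 sweeps;
non-convergence raises a warning and flags the result.

Condition comparisons are displayed as the entrywise log2 ratio of two
balanced maps, Gaussian-filtered with a default standard deviation of 1
bin (the filter width is a display choice, not a statistic). Whether to
smooth before or after the log is a genuinely open choice; terscope
smooths the log2 field, which keeps the antisymmetry
`ratio(a,b) = -ratio(b,a)` exact before smoothing and treats up- and
down-ratios symmetrically. Entries undefined in either map (zero or
masked) are excluded from the kernel, whose mass is renormalized over
the defined entries.

# Range of cis contacts

The statistic asks, for each locus, how far its significant contacts
extend along the genome. The balanced map is binarized at
`median + k * sigma`, with `sigma = 1.4826 * mad` (the robust
standard-deviation estimate; the median absolute deviation is taken
around the median of unmasked entries). The multiplier `k` defaults to
1.0 and is exposed: the robust statistics are fixed by the method but
the multiplier is not, and measured ranges depend on it, so reported
ranges should always cite `k`.

Significant points are grouped by 8-neighbour connected-component
labeling; components smaller than 30 points are noise and dropped;
the surviving mask is closed with a diamond (Manhattan-ball)
structuring element of radius 5 — 61 points — which fills holes inside
elements without bridging well-separated ones. Size filtering precedes
closing. On circular maps both labeling adjacency and the structuring
element wrap across the matrix edges; on linear maps closing pads
erosion with foreground so that it remains extensive (never removes an
original point) at the borders.

The width at bin *i* is measured perpendicular to the main diagonal:
walking `(i+t, i-t)` for `t = 0, ±1, ...`, the maximal contiguous run
of significant points containing `t = 0` has odd length by symmetry
(0 if the diagonal point is not significant). Since the points
`(i+t, i-t)` join loci `2t` bins apart, the range in kb is
`width_bins x bin_size / 2` — 27.5 kb for an 11-wide run at 5-kb
bins. Region summaries use the median and quartiles with
linear-interpolation quantiles (R type 7), the convention used
throughout the package.

# Directional index and CID boundaries

For each bin, contact vectors to the left and right are taken at 5-kb
lags out to 100 kb (20 lags) from the row-row Pearson correlation
matrix of the balanced map, and compared by a two-sided paired t-test
with distance-matched pairing (lag *d* against lag *d*); the sign is
positive when downstream contacts dominate. Display values truncate at
±2 (about p = 0.05 at 19 df). Boundaries are called at sign changes of
the raw t where at least `min_significant_flank` bins (default 3) on
each side are significant at p < 0.05 with constant sign; no
multiple-testing correction is applied, matching the method's use of
a per-bin 0.05 threshold. Masked or zero-variance lags are dropped
pairwise with the degrees of freedom reduced accordingly; on linear
maps, bins within 100 kb of an edge get no value.

One property of this construction deserves emphasis. The correlation
transform gives strong boundary contrast (correlation rows change
sharply across an insulation point) but its p-values are not calibrated
under a homogeneous null: correlation profiles vary smoothly with lag,
so the 20 paired differences are strongly mutually dependent and the
nominal t distribution is badly anticonservative. Running the same
machinery directly on the balanced map (`directional_index(cm)` rather
than `directional_index(correlation_map(cm))`) uses nearly independent
count-derived lags, and there the nominal 5% false-positive rate is
reproduced on homogeneous synthetic maps. terscope therefore treats the
correlation route as the default for boundary *calling* (where flanked
sign changes, not marginal p-values, decide) and the raw route as the
variant of choice when calibrated per-bin p-values matter; the null
calibration check in the test suite uses the raw route for exactly this
reason. For calibration benchmarks the synthetic decay length is kept
large relative to the 100-kb window (lambda = 200 kb) so the paired
differences have comparable variances across lags, as the paired t-test
assumes.

# ChIP enrichment and peaks

IP and input are each scaled by total read count and divided
position-wise; zero-input positions are undefined. The 50-kb centered
sliding window (circular, NA-renormalized, cumulative-sum
implementation) produces the regional profile used for the
replication-following picture; peak calling operates on the
*unsmoothed* enrichment, because the two analyses answer different
questions and a 50-kb window would erase 30-bp features. Peaks are
maximal runs of at least 30 consecutive bp at ≥ 10x background, merged
across the circular origin, with the center at the run midpoint.
"Background" is not defined by the method text; terscope uses the
median of the defined enrichment track, which is total-scale invariant,
and exposes a constant-background override. The 10x rule is applied to
input-normalized signal (a raw-coverage mode can be had by passing the
IP track directly); peak sequences (center ± flank, wrapping) are
exported as FASTA for external motif discovery, which is itself out of
scope.

# matS genomics

The packaged motif is the previously published 13-bp palindromic matS
consensus `GTGACRNYGTCAC`, matched exactly in IUPAC mode on both
strands (ambiguity codes expand in the motif but `N` in the genome does
not match); a position-weight-matrix mode with a score threshold is
available when a matrix is supplied. Perfect-palindrome double hits are
reported once. Scans wrap across the origin of circular genomes.

The Ter domain is the longest stretch of matS sites flanked on both
sides by ≥ 100 kb devoid of sites: sites are clustered at gaps
< 100 kb (including the wrap gap), and the cluster with the longest
first-to-last span wins, ties broken by site count then start
coordinate. Span is measured site-start to site-start; whether
published "Ter size" includes flanking sequence out to the gap
midpoints is not stated anywhere usable, so the site-to-site convention
is used and documented. Summary statistics are the Table-1-style row:
span in kb, site count, sites per 100 kb of Ter, percent of chromosome,
and dif membership. If no gap reaches 100 kb the sites form a single
wrapped cluster, which is opened at the largest gap and reported with a
note that the flanking-gap invariant cannot hold.

Density profiles re-center the circular coordinate on dif and count
sites in contiguous 100-kb windows tiling the circle, window 0 spanning
dif, so every site falls in exactly one window and counts sum to the
site total. Cross-species envelopes are per-offset medians and
quartiles (same quantile convention), using available values at offsets
not present in every species.

# Synthetic data

The generator produces the minimal statistical structure each analysis
assumes, not a physical simulation:

* **Contact maps** — expected counts
  `mu(i,j) = depth * exp(-d(i,j) * bin / min(lambda_i, lambda_j)) *
  prod(insulation)` with circular bin distance `d`, independent Poisson
  draws per unordered pair, symmetrized. The exponential decay is
  chosen over a power law because it makes the width statistic
  analytically tractable — `lambda` is the single knob mapping to the
  measured range, and the mapping is produced by benchmark, not
  assumed. Taking `min(lambda_i, lambda_j)` couples loci so that an
  insulated Ter (default `lambda` factor 0.25, emulating the absence of
  long-range contacts there) restricts contacts of Ter loci with
  everyone. CID boundaries multiply `mu` by an insulation factor
  (default 0.5) for pairs whose shorter arc crosses the boundary edge.
  Defaults: 4.6-Mb circular chromosome (the *E. coli* scale), 5-kb
  bins, `lambda` 200 kb, depth 500 expected counts per bin pair at
  distance zero.
* **ChIP experiments** — flat Poisson input at `depth` reads/bp
  (default 100); IP at `depth` times a fold profile: default 3x
  (middle of the observed 2-4x range) inside the replicated interval,
  baseline inside the Ter-excluded interval, plus optional narrow
  planted peaks. A `noise = "none"` mode returns expectations for
  exactness tests.
* **Genomes** — uniform-random background with concrete motif
  instances written at planted positions, rejection-resampled until no
  spurious matches remain; programmed transpositions excise a segment,
  close the gap and reinsert (optionally reverse-complemented) at the
  original coordinate's gap-closed position, with an exact bijective
  liftover. Coordinates move as in literal string cut-and-paste; the
  convention is pinned by worked examples in the tests because strain
  diagrams of such rearrangements are schematic.

What the generator does *not* emulate — loop extrusion dynamics,
power-law distance decay, replication-fork progression, mappability
artifacts, duplicate reads — bounds what green tests show: they
validate the statistics and algorithms, not the biology of any real
dataset.

# Benchmark sizing

Property benchmarks in the test suite and acceptance script use sizes
chosen for statistical validity first and runtime second:

* SCN balance: 200-bin maps, 50 seeds, `tol = 1e-9` (idempotence is
  then bounded by the row-sum CV times the entry scale).
* The `lambda` recovery sweep (50–400 kb) runs on a 12-Mb chromosome at
  10-kb bins. The global-median threshold requires the significant band
  to stay sparse: counts are nonzero out to roughly
  `lambda * log(2 * depth)`, so the chromosome must be several times
  longer than that for the largest `lambda` (about 2.1 Mb at depth
  100), or the rising global median compresses measured ranges and the
  `lambda`-to-range mapping saturates. A 12-Mb benchmark chromosome
  satisfies this with margin for `lambda = 400 kb`; the Ter-insulation
  contrast, which needs no sweep headroom, runs at the native 1.5-Mb /
  5-kb scale.
* DI calibration: 20 homogeneous 200-bin maps; boundary recovery: 10
  maps with junctions 80 and 120 bins apart.
* Peak exactness: 100-kb tracks at 600 reads/bp with planted folds
  15-30x (margin over the 10x threshold large relative to Poisson
  ratio noise, so the all-30-bp-above-threshold event is essentially
  deterministic) and sub-threshold plants at 9.5x and 29 bp.

# Numerical conventions and degenerate inputs

Coordinates are 0-based half-open internally and in BED/bedGraph
output; bins and fragments are 1-based in genome order. All distances
on circular chromosomes are shortest-arc. Quantiles are
linear-interpolation (type 7) everywhere. The diagonal self-contact
bin is retained in matrices (the width statistic needs it); display
blanking is left to the caller. Zero-variance correlation rows, zero
input positions, empty event lists, single-site Ter domains (span 0,
density undefined) and all-masked maps are handled explicitly rather
than propagating NaN.

# Known limitations

* The measured range of cis contacts depends on the threshold
  multiplier `k`; cross-dataset comparisons must hold `k` fixed.
* Correlation-route DI p-values are anticonservative under the null
  (see above); use the raw route when calibrated p-values are needed.
* The packaged matS consensus is the previously published 13-mer;
  site counts on real genomes depend on the consensus used and exact
  published per-species counts are not guaranteed with the default.
* Multi-chromosome genomes, power-law decay models and
  insulation-score or HMM domain callers are out of scope.
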