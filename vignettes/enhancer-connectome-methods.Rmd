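---
title: "Methods: building enhancer connectomes from HiChIP loops and H3K27ac peaks"
author: "enhancerConnectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building enhancer connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerConnectome)
```

# The problem

H3K27ac marks active enhancers and promoters, and H3K27ac-directed HiChIP
recovers long-range chromatin loops between such regions. Together the two
assays define an *enhancer connectome*: a genome-wide graph whose nodes are
regulatory elements and whose edges are loops supported by ligation read
pairs. This package reconstructs that analysis as a tested pipeline: loop
post-processing (depth normalization, anchor merging, length/strength
filtering), element definition and loop classification (enhancer-enhancer,
enhancer-promoter, promoter-promoter), super-enhancer (SE) calling by
rank-curve inflection, SE-to-target-gene linking with nearest-gene skipping
statistics, paired in-loop looping-factor enrichment, and peak-proximity
expression association. A synthetic-data generator with recorded ground
truth makes every stage verifiable without any external download.

# Coordinates and containers

On disk all formats follow BED conventions: 0-based, half-open intervals in
tab-separated, LF-terminated text (BED/narrowPeak for peaks, 8-9 column
BEDPE for loops, BED6 or headered TSV for TSSs, TSV for expression, JSON for
reports). In memory the package uses the Bioconductor containers the field
standardizes on — `GRanges` for peaks, promoters, TSSs and stitched regions,
plus small S4 classes (`LoopSet`, `ElementSet`, `SuperEnhancerCalls`,
`ConnectomeEdges`) with validity methods for the structures `GRanges` does
not model directly. The IO layer performs the 0/1-based conversion; every
overlap in the pipeline means "at least 1 bp".

# Loop processing

Replicate loop files of one sample are concatenated, with counts summed on
coordinate-identical loops (`concatLoopSets()`). Three operations follow,
with defaults matching the standard HiChIP post-processing recipe:

* **Normalization** (`normalizeLoops()`): counts are scaled by
  `referenceDepth / totalValidPairs`, i.e. rescaled to a common reference
  depth while staying on the read-pair scale. Keeping the read-pair scale —
  rather than, say, counts per million — keeps the conventional retention
  threshold of *three normalized read pairs* meaningful at typical HiChIP
  depths of tens of millions of valid pairs. In a multi-sample run the
  natural reference is the minimum sample depth; a single-sample run uses
  its own depth (normalized = raw).
* **Anchor merging** (`mergeAnchors()`, gap 1500 bp): all anchors of the
  sample are pooled and clustered by single linkage — anchors whose gap is
  at most 1.5 kb join one cluster, transitively — and each anchor is
  replaced by its cluster span. Loops whose two anchors land in the same
  cluster are self-loops and are dropped; loops that become
  coordinate-identical are collapsed with counts summed. After merging, any
  two distinct anchors are separated by more than the gap, which makes the
  operation idempotent.
* **Filtering** (`filterLoops()`): a loop is kept when its length is at
  least 5 kb *and* its normalized count at least 3; both thresholds are
  inclusive. Loop length is the distance between anchor midpoints — a
  definition symmetric under anchor ordering and robust to unequal anchor
  widths (the inner-gap alternative penalizes wide anchors).

# Elements and loop classes

Promoters are symmetric windows of TSS ± 2 kb regardless of strand, clipped
at the chromosome start. Peaks overlapping any promoter window are
promoter-class; all remaining peaks are enhancer-class, so the two classes
partition every peak set exactly. Each loop anchor is labeled `P` if it
overlaps a promoter window, else `E` if it overlaps an enhancer-class peak,
else `O`; precedence P > E > O reflects the convention that promoter overlap
dominates the call. The unordered label pair classifies the loop (EE, EP,
PP, plus the O-containing classes, which are retained and reported
separately so that class counts always sum to the number of loops).
`sharedPeakMatrix()` merges peak sets from several samples into a universe
of single-linkage overlap clusters with a per-sample presence flag, from
which counts such as "common to all samples" follow.

# Super-enhancer calling

`stitchPeaks()` merges enhancer peaks whose gaps are at most 12.5 kb (the
conventional stitching default; TSS exclusion is available but off by
default) and sums constituent signals. `rankSuperEnhancers()` sorts the
stitched regions by total signal and min-max scales both axes of the rank
curve to the unit square. The cutoff sits at the curve's inflection, where
its slope crosses 1: computed as the point of maximum distance below the
scaled diagonal, with ties resolved to the rightmost point (fewer SEs).
This tangency form of the slope-1 rule is used rather than the raw
point-to-point slope because adjacent near-ties — inevitable in any ranked
empirical signal — make the discrete slope dip below 1 spuriously inside
the high-signal block; the tangency point is the same crossing computed
robustly, and it is what practical SE callers implement. Because both axes
are min-max scaled, the calls are invariant under any affine rescaling
`a * signal + b` (a > 0). Regions strictly above the cutoff signal are
super-enhancers. Degenerate inputs are defined: with all signals identical
the cutoff is the maximum (no SEs, with a warning), and with fewer than
three regions no inflection is estimated.

`linkSEToGenes()` reports a link (SE, gene) whenever a loop has one anchor
overlapping the SE region and the other overlapping the gene's promoter
window; supporting loop ids are retained so every link can be re-verified.
`nearestGeneSkipFraction()` then asks, for each SE with at least one linked
gene, whether its *nearest* gene — minimum boundary distance from the SE
region to a TSS, zero inside, ties broken by lexicographically smaller gene
id — is among the linked genes; the skip fraction is the proportion of
linked SEs whose nearest gene is absent.

# Statistics

**In-loop factor enrichment.** For each loop, the span runs from the left
edge of anchor 1 to the right edge of anchor 2. Factor peaks (CTCF/SMC1
style) are assigned by midpoint — so a peak straddling a boundary is counted
exactly once — and the flank control is the mean count of two
similar-sized regions immediately adjacent on either side, each as wide as
the span, clipped at chromosome bounds (a flank clipped to zero width drops
out and the other is used alone). The paired test is the Wilcoxon
signed-rank: zero differences are discarded, absolute differences get
midranks, and W is the positive-rank sum. For effective n of at most 12 the
null is enumerated exactly over all sign assignments; beyond that a normal
approximation with tie correction (variance = sum of squared ranks / 4) and
a 0.5 continuity correction is used — the same conventions as
`stats::wilcox.test`, which the test suite uses as an independent
cross-check. The exact/approximate switch at 12 keeps enumeration cheap
(4096 assignments) while the approximation error is already small; the two
routes agree to about 0.01 in one-sided tail probabilities at n 10-14,
with the usual caveat that mid-range two-sided p-values carry roughly
twice the one-sided discretization error.

**Expression association.** Genes are split by whether any H3K27ac peak
overlaps their strand-aware 20 kb upstream window, and the two expression
groups are compared with a Mann-Whitney rank-sum test (midranks,
tie-corrected normal approximation, continuity correction, one-sided
"greater" in the pipeline). A distribution-free test matches the grouping
design; the original analysis names no specific test, so the rank-sum
choice is this package's, pinned and documented here.

# The synthetic generator

`simulateConnectome()` emulates one sample of such a study on a 10 Mb
chromosome and records everything it plants (`truth`): 300 genes on a
jittered grid (promoter windows never overlap); typical enhancers as ~300
small multi-summit clusters of 2-4 peaks spanning a few kb, with
heavy-tailed log-normal signal (meanlog 0.75, sdlog 0.6); 20 SE loci of 5
constituent peaks each within the stitch distance, signals 80-fold above
the typical scale so the aggregate SE signal is ~50 times the strongest
typical cluster — the 1-2 order-of-magnitude span real hockey-stick curves
show; 1500 loops anchored at peaks and promoters with counts decaying as
distance^-1, plus one high-count planted loop per SE to a promoter — the
nearest gene for 60% of SEs, a farther gene for the planted 40% "skipping"
fraction; 800 factor peaks placed with a 3:1 inside:outside intensity ratio
over the planted loop spans; and log-scale expression elevated by one unit
for genes with a peak within 20 kb upstream. Two replicate loop files with
depths 20M and 15M valid pairs are emitted by binomial thinning so the
replicate-merge and depth-normalization contracts are exercised. Two
placement rules keep the planted truth well-defined at the pipeline's own
stitch scale: cluster loci sit more than 12.5 kb apart, and typical
clusters keep the same clearance from SE spans — otherwise chance chains of
typical peaks become bona fide SE-like structures that no caller could
distinguish from the planted ones.

What the generator deliberately does *not* emulate: multiple chromosomes
(all procedures are intra-chromosomal, and one chromosome keeps fixtures
small), copy-number and mappability artifacts, restriction-fragment
geometry, anchor-level background structure, overlapping gene models, or
correlated replicate noise. Passing recovery tests therefore demonstrates
the pipeline's correctness on data with the assumed statistical structure,
not robustness to every artifact of real HiChIP libraries.

# Numerical choices and degenerate inputs

Thresholds are inclusive throughout (length >= 5 kb, normalized count >= 3).
Midpoints use integer floor of (start + end)/2 in disk coordinates.
Cluster/stitch ties at exact gap equality merge (gap <= limit). The
inflection tie rule is rightmost (fewer SEs). Empty inputs are legal
everywhere they can arise (empty peak files, zero retained loops, no
promoters supplied) and degenerate statistics are defined rather than
errors (all-zero differences give p = 1 with n = 0 and a warning; all-tied
rank-sum gives p = 1). Inter-chromosomal loop rows are skipped with a
logged count rather than modeled.

# Problem sizes

The test suite and acceptance script run the full pipeline on the default
10 Mb / 900-peak / 1500-loop simulation (seconds per run), Monte-Carlo
calibration with 1000 null enrichment simulations of 100 loops each, and
power runs of 200 simulations — sizes chosen so the whole suite completes
in a few minutes on a single core while keeping binomial/Monte-Carlo noise
well inside the asserted tolerances.

# Known limitations

* Loop significance calling from a background model (the job of the
  upstream loop caller) is out of scope; the pipeline consumes called loops.
* The SE cutoff depends on the global shape of the rank curve, so calls on
  subsetted peak sets are not comparable to calls on the full set.
* `recoveryReport()` matches called to planted SEs by any-overlap; with
  very permissive stitching parameters a single called region can match
  several planted loci.
* The enrichment flank control assumes flanks are representative
  background; in real genomes flanking regions can contain other loops'
  anchors, which attenuates the contrast.
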