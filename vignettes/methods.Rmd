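---
title: "Well-formedness analysis of color-space partitions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Well-formedness analysis of color-space partitions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colorpart)
```

## The scientific question

Cross-linguistic color surveys elicit names for a standardized palette of
Munsell chips — canonically 330 of them: a chromatic sheet of 8 lightness
rows by 40 cyclic hue columns, plus 10 achromatic chips.  A long-standing
hypothesis holds that the color categories shared across languages arise
from *optimal partitioning* of color space: category systems are selected
to keep perceptually similar colors together and dissimilar colors apart.
`colorpart` provides the machinery to test that hypothesis computationally:
an objective that scores partitions of the palette, optimizers that search
for the best-scoring partitions, indices that compare a computed partition
with an observed naming system, and null models that calibrate what
"better than chance" means.

## The well-formedness objective

Chips live in CIELAB, where Euclidean distance approximates perceived
color difference.  Perceptual similarity of chips $x, y$ at distance
$d(x,y)$ is

$$\mathrm{sim}(x, y) = \exp\!\left(-0.001\, d(x, y)^2\right),$$

and the well-formedness of a partition $P$ is

$$W(P) = S(P) + D(P), \qquad
S(P) = \sum_{\{x,y\}:\, P(x) = P(y)} \mathrm{sim}(x,y), \qquad
D(P) = \sum_{\{x,y\}:\, P(x) \neq P(y)} \bigl(1 - \mathrm{sim}(x,y)\bigr).$$

Both sums range over *unordered, distinct* chip pairs: each pair counts
once and self-pairs are excluded.  This convention pins down the scale of
$W$ — for 330 chips there are $\binom{330}{2} = 54{,}285$ pairs, and
$W(P)$ plus the complementary sum (within-pair dissimilarity plus
between-pair similarity) equals exactly that constant for every partition,
a conservation identity the test suite exercises on a thousand random
partitions.  Counting ordered pairs or self-pairs would push $W$ past the
values this objective is known to take on the real palette
(roughly 39,000–47,000 for 3–6 categories), which is how the convention
was fixed.  The two components can be reweighted
(`wellformedness(p, sm, weights = c(wS, wD))`) for sensitivity analysis;
all shipped analyses use the canonical unit weights, and the kernel scale
constant 0.001 is likewise exposed but never varied.

Sums over tens of thousands of terms accumulate in compensated (Kahan)
arithmetic in the C++ kernel; equality tests in the suite use a relative
tolerance of $10^{-9}$.

## Optimizers

Three procedures search for high-$W$ partitions at a given category count
$n$; none guarantees the global optimum (the partition lattice is
astronomically large), which is why every stochastic search is a
best-of-many-starts design with per-start seeds derived from one master
seed.

**Particle swarm optimization** (`pso_optimize`).  A particle encodes $n$
centroid triples in CIELAB, each coordinate bounded by the per-channel
min/max over the grid's chips; a particle decodes to a partition by
nearest-centroid assignment (ties to the lowest centroid index) and its
fitness is the $W$ of that partition.  Decoded categories may be empty —
there is deliberately no repair step, and the result records the effective
(non-empty) category count alongside the declared $n$.  Swarm dynamics use
the standard constriction-style constants (inertia 0.729, cognitive =
social = 1.494), 40 particles, absorbing bounds (out-of-box coordinates
are clamped and their velocity zeroed).  Each start additionally screens
100 random centroid sets and seeds one particle with the best of them —
the classic cheap initialization for this objective.  Because the $i$-th
start's stream depends only on (seed, $i$), the first $k$ starts of a
longer run coincide with a $k$-start run, so increasing `n_starts` can
never lower the best $W$ (a property the suite asserts).

**Greedy chip reassignment** (`greedy_reassign`).  Each restart begins
from a uniform random labeling; chips are visited in a fresh random order
every sweep and moved to the label with the greatest strictly positive
$W$ increase, computed incrementally in $O(N)$ per chip from the chip's
similarity-matrix row (`delta_w`); sweeps repeat until one makes no move.
$W$ is non-decreasing within a restart and convergence is guaranteed
because strict improvement is required on a finite lattice.  The
"zero-move sweep" stopping rule and per-sweep re-randomization are the
package's reading of "reassign in random order until convergence"; both
are isolated behind the function's contract.

**k-medoids baseline** (`kmedoids_baseline`).  Classic PAM on the CIELAB
Euclidean distances — an off-the-shelf clustering criterion that does
*not* optimize $W$.  Initial medoids are $n$ distinct chips drawn
uniformly; the swap phase (delegated to `cluster::pam`) descends to a
local optimum of the total distance-to-medoid cost; the best of
`n_starts` starts by that cost is kept and its $W$ *reported* for
comparison.  The special case $n = N$ (every chip its own medoid, zero
cost) is handled directly.

## Comparison indices

Six external cluster-validity indices compare a computed partition with a
reference naming system, all built from one contingency table: NMI
($2I/(H_a + H_b)$), VI ($H_a + H_b - 2I$), split/join (van Dongen,
$2N - \sum_i \max_j n_{ij} - \sum_j \max_i n_{ij}$, reported as an
integer), adjusted Rand, Jaccard and Fowlkes–Mallows over co-clustered
pairs.  Entropies use natural logarithms — that choice is forced by the
analytic VI maxima $2\ln 6 \approx 3.6$ and $2\ln 11 \approx 4.8$ for
balanced six- and eleven-cluster systems, which the acceptance suite
recomputes.  Degenerate conventions: the single-cluster-vs-single-cluster
table scores NMI 1 / VI 0 (the clusterings are identical), and the pair
indices are 0 when no pairs are co-clustered anywhere.  Every index is
validated against two independent brute-force oracles (explicit pair
classification; explicit entropy counting) exhaustively over all partition
pairs of up to 6 items, over a fixed-seed sample of the $877^2$ pairs of
7-item partitions, and over random 50-item pairs.

## Null models and calibration

**Random Voronoi clusterings.**  A null draw samples $n$ points uniformly
in the axis-aligned CIELAB bounding box of the grid (the same box that
bounds the PSO search) and assigns chips to the nearest point.  Empty
cells are kept, not resampled — the draw simply has fewer effective
clusters, and the ensemble records the effective count per draw.
`better_represented_count` asks how many of 1,000 such draws a computed
solution resembles *more* than it resembles the observed naming system;
comparisons are strict (ties do not count), which is the conservative
choice where the published analyses do not state a tie rule.

**Hue rotations.**  Rotating a naming system shifts its chromatic term
assignments $k$ columns along the cyclic hue dimension, preserving
category shapes while breaking their alignment with the geometry of the
chip set; achromatic chips never move.  If categories track the palette's
chroma bumps and depressions, the unrotated system should have the highest
$W$ of its 40 rotations.  Rotation is a group action of
$\mathbb{Z}/C$; the profile records all $C$ values and the arg-max offset
(ties to the lowest).  Rotation refuses grids whose chromatic chips do not
form a full rectangular block, since a cyclic column shift is undefined
there.

**Page's trend test.**  Better-represented counts collected across an
ordered range of category counts form an $m \times k$ matrix (replicates
by ordered conditions); `pages_trend_test` ranks within rows (mid-ranks on
ties) and forms $L = \sum_j j R_j$, with a one-sided p-value from the
normal approximation with continuity correction.  The approximation was
checked against exact permutation enumeration (all $(k!)^m$ rank
configurations) on small matrices; agreement is well inside 0.02.  The
variance formula assumes no ties, so heavily tied small matrices should be
interpreted with care.

## The synthetic generator

Real chip coordinates are third-party survey data and are not bundled, so
the package generates Munsell-like palettes that reproduce the structural
features the analysis depends on (`synth_grid`):

* 8 rows by 40 cyclic hue columns plus 10 achromatic chips (default —
  all dimensions configurable);
* lightness linear across rows over $L^* \in [20, 90]$, achromatic chips
  evenly spaced on the $L^*$ axis;
* base chroma 35 with Gaussian chroma *bumps* on the hue circle, by
  default at 30° and 90° (the red and yellow protrusions of the real
  palette; the green–blue side is correspondingly flatter, which is the
  "depression");
* isotropic Gaussian jitter of sd 1.5 on all coordinates.

These defaults were chosen once to mimic the real palette's scale — and
they land W-optimization in the right regime: optimal $W$ values on the
default synthetic sheet fall within a few percent of those the objective
takes on the real palette.  What the generator does *not* emulate is the
fine colorimetric structure of the Munsell renotation (no attempt is made
to fit the true chroma function), so passing tests demonstrate the
correctness and behavior of the machinery, not colorimetric claims about
real chips.

Two planted-structure generators support recovery testing.
`planted_naming` draws a Voronoi partition of a grid and flips each chip
to a uniformly random *other* label with a given probability, returning
both the noisy naming system and the clean truth.  `synth_blob_grid`
builds $k$ tight Gaussian blobs whose centers are far apart; because the
similarity kernel is wide (sim = 0.5 at distance ≈ 26), "well separated"
is enforced at the kernel scale — default spread 2 and separation ratio 40
put centers ≥ 80 apart, where between-blob similarity is below 0.002 and
the planted membership is unambiguously the $W$-optimal partition.  A
Voronoi partition of the *contiguous* sheet, by contrast, has adjoining
cells and is not a $W$-optimum, so exact-recovery benchmarks use blob
grids.  One caveat worth stating explicitly: with 10% uniform label
noise the expected ARI between the clean truth and the noisy reference is
only ≈ 0.72–0.79 (depending on $k$), so even a perfect optimizer cannot
systematically exceed 0.8 against a noisy reference under this noise
model; recovery claims in the test suite are therefore sharp at noise 0
and descriptive at noise 0.1.

All generators are pure functions of (spec, seed); per-operation streams
are derived from the master seed and an operation tag, so changing the
effort of one stage never perturbs another.

## Reporting conventions

A category is displayed with the color of the chip nearest (over the whole
grid, not just the category) to the category centroid, defined as the
coordinate-wise mean of the member chips' CIELAB triples — the mean, not
the distance-sum minimizer, which is the other definition sometimes seen
for "centroid"; the two differ in general and the package commits to the
mean.  Text rendering assigns glyphs by descending category size for
stable diffs; image rendering converts the representative chips to sRGB
(clipping into gamut).

`run_pipeline` orchestrates the full study — optimize across a range of
$n$, compare against references, build ensembles, scan rotations, run the
trend test — and stamps every artifact with a hash of its configuration
and the master seed, so deleting outputs and rerunning reproduces them
byte for byte.

## Problem sizes and numerical choices

The shipped analyses and tests run at deliberately moderate effort,
chosen as the package's own default study sizes: PSO with 40 particles,
120–200 iterations and 2–3 starts (plus 100-candidate start screening),
greedy with 10–20 restarts, PAM with 50–200 starts, ensembles of 300–1000
draws.  The published analyses this machinery descends from used heavier
settings (100 PSO starts, 2,500 PAM starts, 1,000 draws), and all of
those are the function defaults — the lighter settings are used where a
full suite must run in minutes, and on the well-separated benchmarks they
already achieve exact recovery.  Other fixed choices: nearest-centroid
and nearest-point ties break to the lowest index; greedy requires strict
improvement (tolerance $10^{-12}$) to move; modal-term ties in
`mode_map` break lexicographically, making the result independent of
speaker order.

## Known limitations

* The real survey chip chart and observed mode maps must be supplied by
  the user (`read_chip_coordinates`, `read_naming_table`); published
  values tied to those files can only be recomputed when the files are
  present.
* PSO on 33-dimensional centroid encodings can lodge in local optima at
  low start counts; the $n = 3$ regime is known to be multi-modal.
* VI's triangle inequality and the indices' ranges are verified on random
  instances, not proven here for every degenerate table shape.
* Page's test p-values rely on the no-ties variance; exact enumeration is
  provided in the test oracles for small shapes only.
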