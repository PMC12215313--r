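---
title: "Detecting architectural stripes in contact maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting architectural stripes in contact maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HiCstripes)
```

## Background

Architectural stripes are narrow rectangles of enriched contact frequency
anchored at the main diagonal of a Hi-C or Micro-C contact matrix. They arise
from one-sided loop extrusion: cohesin extrudes a loop until it is blocked on
one side by a CTCF-bound site, while extrusion continues on the other side,
sweeping out contacts between the blocked anchor and progressively more
distant loci. In the matrix this produces a vertical stripe below the
diagonal (or, for barriers blocking the opposite direction, above it), a few
bins wide and often hundreds of kilobases tall.

`HiCstripes` detects these patterns with a geometric pipeline rather than
image processing, computes shape and intensity descriptors for each
candidate, and ships a benchmarking layer that scores calls against
ground-truth extrusion barriers, together with a synthetic map generator for
controlled evaluation.

## The calling pipeline

Calls run independently on the lower and upper triangles of a diagonal band
of each chromosome's contact matrix, in four steps.

**Step 1 — preprocessing.** Raw counts in a band around the diagonal
(default half-width 5 Mbp, chosen to upper-bound mammalian TAD sizes) are
mapped through `log(1 + v)` and divided by the maximum, giving values in
$[0, 1]$. `log1p` is used because banded contact matrices are dominated by
zeros; dividing by the maximum (rather than min–max scaling) keeps the
denominator well defined when all stored counts are equal. The transform is
strictly monotone, so it reorders nothing.

**Step 2 — seeds.** Each triangle is marginalized by summing over the rows,
giving a scalar profile over the columns. Sparse columns produce spurious
dips, so the profile is corrected to the pointwise maximum of itself and its
weighted moving average (symmetric triangular kernel, default half-width 2
bins; the kernel fills dips but never erodes peaks), then rescaled to
$[0, 1]$. Candidate anchors — *seed sites* — are the local maxima of this
pseudo-distribution that survive filtering by one-dimensional topological
persistence: sweeping a level from the top downward, each local maximum
births a connected component, and when two components merge the lower one
dies; a maximum's persistence is the gap between its height and its merge
level. Maxima with persistence below the threshold (default 0.04, i.e. 4% of
the profile maximum) are treated as fluctuations. The global maximum never
merges and is always retained. Two deterministic conventions make the result
unique and testable against a brute-force reference: a plateau of equal
values counts as one maximum at its leftmost index, and when two maxima of
equal height merge the leftmost survives. Zero-persistence classes (a
plateau flowing directly into a higher region) are diagonal pairs of the
filtration, not maxima, and are discarded.

**Step 3 — geometry.** The *horizontal domain* (stripe width) follows the
pseudo-distribution away from the seed through its maximal non-decreasing
run (towards the seed) and places the boundary one bin past the steepest
rise on the left and one bin before the steepest fall on the right; ties are
broken towards the seed, and the domain is clipped symmetrically around the
seed to `max_width` (default 100 kb), which prevents stretching at coarse
resolutions. On sampled data a strictly monotone run would stop at the first
shot-noise dip inside a stripe's own plateau and collapse the width to one
bin; the run therefore bridges counter-movements up to a tolerance equal to
the persistence threshold — exactly the fluctuation scale the seed filter
already deems insignificant. Setting the tolerance to zero restores the
strict rule.

The *vertical domain* (stripe height) marginalizes the columns of the
horizontal domain per row-offset from the seed's diagonal position (downward
in the lower triangle, upward in the upper), rescales the offset profile to
$[0, 1]$, and bounds the stripe either where the profile first drops below
`min_value` (default criterion, cutoff 0.1) or, optionally, at the
persistent peak farthest from the diagonal; with the persistence criterion
the remaining off-diagonal peaks are reported as interior peaks, marking
sharp signal increases inside the stripe.

**Step 4 — descriptors.** On raw counts (so that enrichment is measured on
the original scale), each stripe rectangle yields its five-number summary,
mean and population standard deviation, plus the mean over the *k-neighbour*:
the `k` columns flanking the domain on each side over the same vertical
extent. The default `k` equals the stripe's width, making the comparison
area-matched. The *relative change*,
$100 \cdot (\bar{x}_{in} - \bar{x}_{out}) / \bar{x}_{out}$, is the
post-filter score: the recommended cutoffs are 4% for simulated maps and 3%
for real maps, and raising the cutoff only removes calls. Flanks truncated
by the chromosome edge fall back to the remaining flank; when both are
empty the relative change is reported as `Inf` for a positive inner mean
and 0 otherwise.

### Parameter summary

| parameter | default | units | role |
|---|---|---|---|
| `band_width` | 5e6 | bp | diagonal band half-width (TAD-scale upper bound) |
| `persistence_threshold` | 0.04 | fraction of profile max | seed filter; also the run tolerance in width estimation |
| `max_width` | 1e5 | bp | cap on stripe width |
| `vertical_criterion` | `"threshold"` | — | height rule (`"persistence"` optional) |
| `min_value` | 0.1 | fraction of offset-profile max | height cutoff for the threshold rule |
| `wma_half_width` | 2 | bins | moving-average kernel half-width |
| `k_flank` | `"match-width"` | bins | flank width for descriptors |
| `use_balanced` | `FALSE` | — | raw counts by default; the caller behaves best without prior balancing |

## The synthetic map generator

`generate_map()` is a statistical surrogate for extrusion-based simulators,
not a kinetic model: it reproduces the features the caller and the metrics
react to, at desk scale. The background expected count at diagonal distance
$d$ bins is $C (1 + d)^{-\alpha}$ (default $\alpha = 1$, the canonical
contact-decay exponent), rescaled so the band-wide mean equals the contact
density $\delta$ (default 1 count per pixel — a sparse, demanding regime).
Each planted stripe multiplies the mean inside its rectangle by
$1 + s \cdot \mathrm{occupancy}$ with enrichment factor $s = 5$, so an
occupancy of 0.8 gives a five-fold enrichment. Counts are Poisson draws;
the map is symmetric, so the upper band is the mirror of the lower and each
planted stripe also appears, transposed, in the opposite triangle — exactly
as in real data. Displacement noise moves every sampled contact along both
axes by a signed geometric number of bins with mean $\sigma$; contacts
displaced out of the band are lost. The generator's default band half-width
is 500 bins, the caller's 5 Mbp band at the default 10 kb resolution, so
desk-scale maps are not artificially truncated relative to the caller.

What the generator does *not* emulate: TADs and compartments, balancing
artefacts, restriction-fragment structure, genome-wide scale, or the
kinetics of extrusion. Passing tests on these maps therefore demonstrate
the pipeline's geometric and statistical behaviour under a controlled
silhouette of real data, not performance on real contact maps.

## Evaluation studies and their design

`planted_recovery_study()` plants ten well-separated stripes (anchors at
least 10 bins apart, widths 2–4 bins, heights 200–600 kb, occupancy 0.9–1)
in 500-bin maps at 10 kb with $\delta = 1$ and no displacement noise, calls
stripes with all defaults, filters at a 4% relative change, and reports the
anchor hit rate (AHR: fraction of planted anchors inside at least one called
horizontal domain), the fraction of good candidates (FGC: fraction of calls
containing a planted anchor) and the width-recovery rate (fraction of
matched stripes whose called width is within one bin of the planted width).

A known limitation shows up here: at one expected contact per pixel the
Poisson fluctuation of the marginal profile sits at roughly 3% of the
profile maximum — the same scale as the 4% persistence threshold — so a
sparse map yields a tail of spurious seeds. Their width-one rectangles are
centred on selected local maxima, which biases their relative change well
above the 4% cutoff, so the post-filter does not remove them either. With
only ten true anchors per map, FGC consequently plateaus far below one in
this regime even though AHR and width recovery are high; both thresholds
are kept at their standard defaults rather than tuned per dataset. On dense
ground truths (anchors in a sizeable fraction of bins, as in genome-scale
benchmarks) the same calling behaviour yields a high FGC because false
calls usually land on some anchor.

`noise_degradation_study()` measures how AHR decays as $\sigma$ grows
across $\{0, 1, 3\}$ over ten seeded maps per level. Its map population is
deliberately different: twenty stripes per map (AHR granularity 0.05
instead of 0.1), occupancies spanning the full realistic spectrum 0.2–1,
and heights of 100–500 kb. With near-saturating barriers (occupancy
$\ge 0.9$) every stripe sits far above the detection boundary and the
readout pins at 1.0 for small $\sigma$; spanning the occupancy spectrum
places part of the population near the boundary, where noise acts. Stripe
placements are shared across noise levels for a given seed, so the
comparison is paired.

## Numerical conventions and degenerate inputs

* Bin indices are 0-based internally; exported genomic intervals are
  0-based half-open bp (BED/BEDPE convention).
* Quartiles use linear interpolation (R type 7); standard deviations use
  the population form.
* Undefined metric ratios (zero denominators) are `NaN` and propagate into
  derived measures; they are never silently converted to 0.
* Ground-truth barriers falling in the same bin with the same blocking
  direction collapse to one anchor with the mean occupancy; opposite
  directions stay separate. Occupancy stratification (cutoff 0.70) is
  available in `benchmark_report()`.
* Metrics pool the two triangles micro-style: confusion counts are summed
  before ratios are taken.
* An all-zero triangle raises a typed condition and the chromosome is
  skipped with a message; a seed with an empty column set yields a
  height-one domain at the diagonal.
* Archives reject unknown format versions by name; empty tables are
  represented by the dataset's absence.

## Problem sizes

The default studies use 500-bin chromosomes (5 Mb at 10 kb): large enough
for dozens of simultaneous stripes and full-depth marginals, small enough
that the complete test suite and the evaluation studies run in a few
minutes on a single core.

## Limitations

* The FGC plateau on sparse maps discussed above: on low-depth data the
  caller trades precision for sensitivity, and the relative-change filter
  cannot restore precision for width-one candidates.
* `.hic` (Juicer) input is not supported; use `.cool`/`.mcool` or the text
  COO fixture format.
* Matrix balancing is not implemented; stored cooler weights can be applied
  on request, but the method is designed for raw counts.
* Stripes are assumed anchored at the diagonal; detached linear features
  are out of scope.
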