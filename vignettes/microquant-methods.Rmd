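---
title: "microquant: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{microquant: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microquant)
```

This vignette records the measurement models microquant implements, the
conventions it fixes where the field's literature leaves a choice open, and
the numerical decisions that make its exactness contracts testable. It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

## Data model and coordinates

All images are dense arrays in `(z,) y, x` axis order with 0-based
pixel-center coordinates; bounding boxes are half-open `[min, max)`. An
intensity image stores values in `[0, 1]` together with the grey-level
count of its source (256 for 8-bit, 65,536 for 16-bit); integer TIFFs are
rescaled by their dtype maximum on reading, float TIFFs are assumed
pre-scaled and are clipped to `[0, 1]` with a warning (their grey-level
count defaults to 256 unless overridden, matching the historical 1/255
threshold-scan step). The grey-level count is not cosmetic: it defines the
candidate grid of every threshold search. A label image is a non-negative
integer array; 0 is background and objects cannot overlap within one label
image — which is exactly why combining two label images requires an
overlap-resolution policy.

## Combining object sets

The disputed region of two object sets is the intersection of their
foregrounds. The four strategies resolve it as follows, with output ids
relabeled sequentially in (source set, original id) order:

* **preserve** — initial pixels are inviolate; each addition object keeps
  only its pixels outside the initial foreground and vanishes if fully
  covered.
* **discard** — addition objects touching the initial foreground at even
  one pixel are dropped whole.
* **merge** — starting from the preserve assignment, each disputed pixel
  is reassigned to the initial-set object with the nearest *undisputed*
  pixel (exact squared Euclidean distance; ties to the lower-ranked
  object). Output objects from different source sets that touch under the
  chosen connectivity then fuse — including two initial objects bridged by
  an addition object, since fusion runs on the cross-set adjacency graph.
  Two initial objects that merely touch each other never fuse.
* **segment** — the union foreground is re-segmented: every object's
  undisputed pixel set is a seed, and disputed pixels go to the nearest
  seed. Objects with no undisputed pixels have no defensible claim and are
  dropped.

Distances come from a separable exact Euclidean distance transform
(lower-envelope algorithm, one pass per axis), computed per seed object.
Because seed costs are 0 and pixel spacing is 1, all squared distances are
integers, so distance ties are detected exactly and broken
deterministically toward the earlier object. The test suite checks the
assignment against an exhaustive per-pixel nearest-seed search on 32×32
grids.

One degenerate case needs a policy: if the two foregrounds are identical,
*no* object has an undisputed pixel, and dropping all seedless objects
would empty the output, violating foreground conservation. In that case
disputed pixels keep their initial-set owner and only addition objects are
dropped — mirroring merge, and keeping the conservation law exact:
the output foreground equals the union of the input foregrounds for
merge/preserve/segment, and the initial foreground plus kept addition
objects for discard.

Connectivity defaults to full (8-neighbor in 2D, 26 in 3D), the visual
notion of "touching"; face connectivity (4/6) is available.

## The thresholding engine

**Otsu.** The two-class threshold maximizes the between-class variance
over an `nbins` histogram spanning `[min, max]` of the image
(`nbins = min(grey_levels, 256)` by default — exact for 8-bit data,
tractable for 16-bit). The returned value is an interior bin edge, so it
lies strictly between the image extremes; ties take the lowest edge.
Constant images raise a degenerate-input condition rather than returning
an arbitrary number. The implementation (vectorized cumulative sums) is
tested against an exhaustive search over all candidate edges.

**Adaptive mode.** Any global method can run blockwise: the image is tiled
into `window`-sized blocks, the method runs per block (degenerate blocks
inherit the whole-image threshold), and block-center thresholds are
interpolated multilinearly with edge clamping — the minimal smooth
interpolant, since nothing in the method constrains the choice. The
surface is clamped to `[global·low, global·high]` with defaults
`(0.7, 1.5)`: local thresholds in empty or pathological blocks should not
run away from the global estimate, and bounds `(1, 1)` provably collapse
the surface to the global threshold, which the tests assert. The window
must be at least 8 pixels and smaller than every image axis; a smaller
image should simply use the global method.

**Sauvola.** `T = m·(1 + k·(s/R − 1))` per pixel, with `m`, `s` the mean
and standard deviation over an odd window with symmetric (reflective)
border padding, via separable sliding sums. Defaults `k = 0.2`,
`R = 0.5` (half the 0–1 dynamic range) and window 25 follow the method's
standard parameterization. A constant image gives the closed form
`T = c·(1 − k)` everywhere.

**Log transform.** Any global method can be computed on
`x → log(x + ε)` rescaled to `[0, 1]` with `ε = 1/grey_levels`; the
returned threshold is mapped back through the exact inverse. The wrapper
makes the transform explicit rather than an implicit property of one
method, so Otsu values match what other software reports unless the user
asks for the log domain.

**Application.** Foreground is `value > threshold`, strictly — fixed so
masks are bit-reproducible; consequently threshold 1 yields an empty mask
and raising any threshold never adds foreground.

## Costes automated thresholds

The coupling line `tB = a·tA + b` comes from orthogonal (total least
squares) regression of B on A — the major principal axis of the joint
distribution, the canonical choice for two noisy channels; ordinary least
squares is available as an option. The below-threshold set at candidate
`tA` is `{a ≤ tA and b ≤ a·tA + b}` — both channels jointly below, the
common published reading, fixed here for testability. Sets with fewer than
two pixels or a constant channel have an *undefined* correlation (`NA`),
which the searches skip; undefined never counts as "≤ 0", preventing
spurious early convergence on sparse tails.

All four searches share one candidate grid — the representable grey levels
of channel A, `t_k = k/(G − 1)` — and one engine: for positive regression
slopes, pixel membership is `t ≥ max(a_i, (b_i − b)/a)`, so the sets are
nested and sorting by that entry value gives the count and the Pearson
correlation of every candidate set from prefix sums in constant time. For
negative slopes (possible near zero correlation, where the TLS axis is
unstable) membership is an interval in `t` and the same machinery runs on
entry/exit orders. An *evaluation* is one Pearson computation on a
distinct valid set; revisiting an unchanged set is free in every mode,
which is precisely the accurate-mode insight.

* **canonical** re-evaluates every fixed-step candidate (step 1/255 by
  default) from `max(a)` downward and stops at the first correlation ≤ 0.
* **accurate** walks every grey level but evaluates only when the pixel
  count changes; since an unchanged count means an unchanged (nested) set,
  the returned threshold equals the exhaustive scan's by construction.
* **fast** grows its step with the last correlation
  (`max(1, floor(r/0.35) + 1)` grey levels — unit steps below 0.35, a
  configurable constant), keeps the count-change gate, and on the first
  non-positive correlation backtracks to the previously evaluated
  candidate for a unit-step rescan.
* **faster** runs a weighted bisection on the window
  `[min(a), max(a)]`: after a warm start (the top candidate plus up to
  three count-change candidates below it, so thresholds at the very top
  cost no more than a plain scan), each cycle evaluates one candidate in
  the upper sixth of the window; a positive correlation discards the upper
  ~1/6, otherwise the lower ~5/6 goes. The window shrinks by at least 1/6
  per cycle — hence the cycle bound `ceil(log G / log(6/5))` plus a
  terminal unit-step scan of the last few grey levels.

**What equivalence can and cannot mean.** If the correlation profile
crosses zero once (all candidates above the crossing positive, all below
non-positive), every mode provably returns the same threshold: accurate
stops exactly at the crossing, fast's backtrack re-finds it, and the
bisection invariant keeps it inside the window. On profiles that *graze*
zero — dip marginally below and recover — a bisection can land on a lower
crossing; this is the documented overshoot risk of accelerated searches,
intrinsic to the algorithm and not an implementation defect. The test
suite therefore asserts exact identity on every generated pair whose
profile is single-crossing, asserts canonical-accurate identity on all
8-bit pairs (their candidate grids coincide), reports the overall
agreement rate, and logs the non-monotone overshoot pairs as an audit.
The evaluation-count ordering faster ≤ fast ≤ accurate ≤ canonical is
likewise asserted on single-crossing profiles (modes that stop at
different thresholds do incomparable amounts of work).

Manders coefficients `M1 = Σ a·[b > tB]/Σ a` (M2 symmetric) default to
per-channel Otsu thresholds when none are supplied; the Costes
coefficients C1/C2 are the same quantities computed at the automated
thresholds `(tA, tB)`.

## Per-object texture

Each object's intensities are quantized into `levels` bins (default 8, a
conventional co-occurrence resolution) over the object's *own* min/max —
per-object masked semantics, with a closed top bin and constant objects in
bin 0. Grey-level co-occurrence matrices count ordered pairs
`(p, p + offset)` with both pixels in the object mask, symmetrized and
normalized; default offsets are the four classical 2D directions at
distance `scale` (default 3), with an axial z offset added in 3D. The 13
Haralick statistics use base-2 logarithms with `0·log 0 = 0`; a one-hot
matrix reports correlation 0 (zero-variance convention), and an empty
matrix (no valid pair) yields all-zero features with a flag column. The
14th classical feature (maximal correlation coefficient) is omitted as
numerically unstable, the standard practice.

The cropped mode computes all of this inside the object's bounding box
expanded by the largest offset component — the expansion guarantees every
within-mask pair is representable in the crop. Equality with the
full-array mode is exact, not approximate: quantization depends only on
masked values, co-occurrence counts are integers accumulated into an
`L×L` table (order-independent), and the feature arithmetic then operates
on identical matrices. The suite asserts `identical()` on 50 fixtures
including touching, border-clipped and 3D objects.

## Shape measurements

Moments are sums over pixel-center coordinates: central moments `mu_<pq(r)>`
to total order 3, normalized moments `eta = mu / n^(1 + order/ndim)`, and
the inertia tensor as the coordinate covariance matrix with eigenvalues
sorted descending; eccentricity (2D) is `sqrt(1 − λ_min/λ_max)`. All are
tested against brute-force summation.

The Euler number is computed by topological cell counting, not lookup
tables. Under full connectivity, pixels are closed unit squares/cubes and
the characteristic is `V − E + F (− C)` over the distinct cells of their
union (closed cubes sharing only a corner are connected — exactly the
8/26-neighbor notion). Under face connectivity the dual complex is used:
pixels as vertices, face-adjacent pairs as edges, full `2×2(×2)` blocks as
squares/cubes. A square ring gives 0, a hollow 5³ shell gives 2, and the
count is additive over disjoint objects; the tests check random masks
against an independent cell-enumeration oracle.

Solidity divides the object size by the pixel count of its filled convex
hull. The hull is taken over the *corner points* of the object's pixels
and filled by boundary-inclusive center testing — the convention under
which convex digital shapes (rectangles, boxes) score exactly 1 and the
3×3 "plus" scores 5/9. (A center-point hull would make the plus score 1,
collapsing the measure for small objects.) Coordinates are doubled
internally so all orientation tests run on integers and are exact. 2D
hulls use Andrew-style hull vertices from `grDevices::chull`; 3D hulls use
an incremental algorithm seeded with an extreme tetrahedron, with
candidate points pre-filtered to those extremal on every axis line through
them (a filter that provably retains all hull vertices). Collinear and
coplanar objects are hulled in their affine span; objects of at most two
pixels score 1 by convention. Note that only *axis-aligned* lines are
degenerate under corner points: a diagonal line's corner hull is a band
that contains off-diagonal centers, so its solidity is below 1, as in
standard convex-hull-image implementations.

Perimeter (2D) is crack length — the number of unit pixel edges exposed to
background or the image border — a simple, exactly reproducible
convention; form factor `4π·size/perimeter²` consequently reads about 0.6
for digital discs rather than 1, which is documented rather than hidden by
a calibration factor.

## Synthetic fixtures

The generators produce every input the tests need, deterministically under
a seed (the RNG state is saved and restored, so they never perturb a
session's randomness).

**Blob labels** place random discs/spheres with radii in a range;
non-touching placement uses rejection with a one-pixel clearance (so the
component count equals the object count), and options allow touching,
overwriting and border-clipped objects — the stress cases for the texture
crop contract. **Object pairs** place matched discs at a center distance
solved (by bisection on the continuous lens-area formula) to hit a target
intersection-over-union; pairs are laid out in non-interacting cells, and
pixelation keeps the realized IoU within about 0.1 of the target at the
default radii.

**Correlated channel pairs** emulate fluorescence images: sparse bright
spots (Gaussian bumps truncated at 3σ, so structures have compact support)
over a dim, spatially correlated noise background. The shared field
carries colocalized structures only — real background noise is channel
independent — and each channel additionally receives a mild *exclusion
imprint* of the other channel's structures
(strength `0.3·sqrt(1 − |ρ|)`, capped so the channel-specific component
keeps ≥ 5% of the variance), emulating volume exclusion or bleed-through
compensation. The construction mixes *orthonormalized realized fields*, so
the sample Pearson correlation equals the requested ρ exactly before
quantization; min-max rescaling is affine and preserves it, and grey-level
rounding perturbs it by well under 0.05 at 64×64. The design intent of the
exclusion term is qualitative, not a tuning knob: it makes the
below-threshold correlation of background-only pixel sets slightly
negative, so Costes profiles cross zero decisively at the
structure/background boundary — the regime in which the search strategies
are specified to agree. What these fixtures do *not* emulate: shot noise,
detector offsets, uneven illumination, and textured biological background;
passing the equivalence suite on them shows algorithmic correctness in the
single-crossing regime, not robustness of Costes thresholds on arbitrary
real data (profiles that graze zero will differ between accelerated and
exhaustive searches on real images too).

## Problem sizes and determinism

The acceptance computations use 100 correlated pairs at 64×64 (correlation
0–0.9, 8- and 16-bit), 50 texture fixtures at 40×40 and 16×18×18, 50
combination pairs at 32×32 with the exhaustive oracle, and small closed-form
shapes — sizes at which every oracle is exact and the whole suite runs in a
few minutes on one core. Every CLI run writes a JSON parameter echo beside
its outputs, and rerunning any synth + measure pipeline with the same seed
produces byte-identical TIFFs and CSVs, which the suite asserts with raw
file comparison.

## Known limitations

* Costes accelerated modes can overshoot on profiles that graze zero (see
  above); the package reports them rather than pretending universality.
* The accurate-mode skip gate is on the below-set *pixel count*; for
  negative regression slopes (near-zero correlation) two different sets
  could in principle share a count between consecutive candidates. The
  situation requires the TLS axis to be flipped, where Costes thresholds
  are of little scientific use anyway.
* Perfectly anti-correlated pairs (`b = 1 − a`) degenerate under the
  joint-below coupling: every candidate set collapses to at most one
  pixel, so all searches run dry and report non-convergence — consistently
  across modes, but without a threshold.
* 3D perimeter/surface area, Feret diameters and Zernike moments are out
  of scope; eccentricity, perimeter and form factor are 2D-only.
* The solidity hull is exact for integer pixel geometry but the 3D
  incremental hull has not been hardened for objects with millions of
  boundary corners; typical segmented objects are orders of magnitude
  smaller.
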