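---
title: "Consensus aggregation for crowdsourced volumetric annotation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus aggregation for crowdsourced volumetric annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdvol)
```

`crowdvol` turns a 3D grayscale volume into classification subjects for a
citizen-science platform and turns the volunteers' responses back into
consensus results in volume coordinates. This vignette explains the models
behind each stage, the parameters that matter, and the choices made where
the design was genuinely open.

## Conventions

Axes are `(z, y, x)`, 0-based, with y increasing downward, matching raster
image files. Intensities are floating-point throughout; quantisation (8-bit
for PNG subjects, 16-bit for TIFF volumes) happens only on export, by
round-half-up. Pixel `(i, j)` occupies the unit square with centre
`(i + 0.5, j + 0.5)`; every inside/outside decision in the package is made
at pixel centres, which keeps rasterization, consensus and evaluation
mutually consistent.

## Subject generation

### Tiling

`plan_tiles()` covers a padded plane with tiles whose origins advance by
`stride = tile * (1 - overlap)`. The frame is padded on each side by the
overlap width `tile - stride`, and the final origin per axis is clamped so
the last tile flushes the padded edge — duplicating coverage rather than
truncating it. At the default `overlap = 0.5` every original pixel lies in
at least two tiles (four away from degenerate cases), and any pixel within
`stride / 2` of one tile's edge sits at least `stride / 2` from every edge
of some neighbour: edge features are always central somewhere. The
per-pixel multiplicity is reported (`tile_coverage()`) because an operator
may lower the retirement limit in proportion to the redundancy; the package
reports, it does not decide.

The stride must be a whole number of pixels (`tile * (1 - overlap)`
integral); fractional strides are refused rather than rounded, so tile
coordinates remain exact.

### Flipbooks and z sampling

A flipbook stacks `2h + 1` consecutive slices (default `h = 2`, five
frames) and is annotated on the central plane; the outer frames are 3D
context only, and only the annotation plane enters aggregation. Centres
closer than `h` to the stack ends are refused outright — annotation quality
degrades near stack boundaries, and silently clamping would hide that —
so shallow volumes yield fewer (or zero, with a warning) subjects.
`sample_z()` enumerates valid centres at a chosen stride; the stride is
recorded in the manifest because skipping slices distorts the z scale, and
downstream clustering undoes it via the anisotropy factor (below).

### Size validation

Subject media must stay small for contributors on limited bandwidth:
`validate_subject()` grades the total encoded bytes of a subject's frames
as `ok` below 600 KB, `warn` in [600 KB, 1 MB), `error` at or above 1 MB.
The totals are computed from the actual encoded PNG frames
(`encode_subject()`), not estimated.

## The export dialect

Classification exports are CSV with one row per volunteer response:
`classification_id`, `user_name`, `workflow_id`, `workflow_version`,
`created_at`, `annotations` (JSON array of `{task, value}`), `subject_data`
(JSON), `subject_ids`. Value shapes map to typed records: `{x, y, frame}`
is a point, `{x, y, rx, ry, angle, frame}` an ellipse,
`{points: [...], frame}` a freehand line, a bare string an answer.
Malformed rows are collected in a rejected-row report with reasons — never
silently dropped — and `#parsed + #rejected = #rows` always holds.
Contributor names are pseudonymised on ingest with a salted FNV-1a hash;
rows without a login become one distinct pseudo-contributor each, which
prevents all anonymous traffic collapsing into a single "contributor" whose
vote would be both undercounted and overweighted. Workflow versions compare
numerically per dotted component (10.1 > 2.3).

## Question consensus and early retirement

`majority_vote()` takes the modal choice; ties break to the
lexicographically smallest choice and are flagged so analysts can exclude
them. Early retirement uses the lead-vs-remaining criterion: with `n` of
`N` votes cast and top-two counts `c1 >= c2`, the subject may retire iff

    c1 - c2 > N - n.

This is the weakest condition that still guarantees no completion of the
remaining votes can change the winner (ties broken as above); the package
verifies this by exhaustive completion enumeration in its test suite. For a
unanimous opening the bound gives `floor(N / 2) + 1`: three identical votes
suffice at `N = 5`, four at `N = 6`. Votes are ordered by `created_at` and
deduplicated to one per contributor per subject (earliest kept, ties by
classification id) before any of this runs.

## Point aggregation

Volunteers mark object centres; distinct volunteers' marks of the same
object land close together while individual errors land alone. DBSCAN
separates the two regimes: core points have at least `min_samples`
neighbours within `eps` (inclusive, counting themselves), clusters are
connected components of cores under eps-adjacency plus attached border
points, everything else is noise and is discarded as outlier marks.
The implementation follows the density-reachability definition directly
(no library delegation) so that the test suite's brute-force
reachability-closure oracle is a meaningful independent check. Noise is
labelled `0`, cluster ids `1..k`, the convention of R clustering tools.

Distances are `sqrt(dx^2 + dy^2 + (a * dz)^2)`: the anisotropy factor `a`
defaults to the manifest `z_stride`, restoring metric comparability when
not every slice was sampled. Each cluster yields one detection at the
arithmetic mean of its member positions; support counts *distinct
contributors*, so one volunteer double-marking cannot manufacture support.
Defaults: `eps` should be on the order of the expected object radius
(operator-supplied; there is no universal value), and
`min_samples = ceiling(retirement_limit / 2)` mirrors majority logic.
Ellipse marks contribute their centres; semi-axes are retained for
bounding-box export.

A second workflow may present each detection for label voting
(`vote_object_labels()` reuses the majority machinery); detections whose
winning label is a designated rejection choice can be dropped, giving an
automated cleaning pass.

## Contour consensus (CRIA)

Freehand outlines differ from points: correct annotations overlap heavily,
so consensus is computed pixelwise.

1. **Closure** (`close_polyline()`): strokes whose endpoints already
   coincide are loops; endpoint gaps up to a tolerance (default 5% of the
   frame diagonal) are closed by appending the first vertex; anything wider,
   or with fewer than three distinct vertices, is rejected with a reason and
   reported. Guessing at a wildly open stroke would fabricate area, so the
   package refuses instead.
2. **Interior** (`rasterize_interior()`): a pixel belongs to the interior
   iff its centre is inside the polygon under the even-odd rule — chosen
   because volunteer strokes self-intersect, and even-odd is deterministic
   and orientation-independent there. Implemented as a scanline with the
   half-open edge rule; the suite checks it pixel-for-pixel against a naive
   point-in-polygon oracle.
3. **Height map** (`height_map()`): per-pixel count of contributor
   interiors. A contributor's multiple loops on one frame are OR-ed first,
   so `N` counts contributors, not strokes.
4. **Threshold** (`cria_consensus()`): keep pixels where half or more
   volunteers agree, `2 h >= N`, inclusive. With even `N` this keeps
   exact-half pixels; at `N = 2` the consensus is the union of both
   interiors. That is a direct consequence of "half or more" and is kept
   deliberately; a strict-majority variant would instead return the
   intersection at `N = 2`. (Reading the threshold as the *mean of observed
   heights* rather than `N / 2` was considered and rejected: it would make
   the criterion dependent on how much empty frame the raster happens to
   include.) The agreement raster `h / N` accompanies the mask.

Outlier annotations are removed by a two-pass scheme
(`remove_outlier_annotations()`): compute a provisional consensus over all
masks (or use an expert mask when available), exclude masks whose IoU with
that reference falls below a cutoff (default 0.3 — low enough that honest
boundary disagreement survives and only off-structure scribbles fail),
recompute once on the survivors. A single pass is deliberate: iterating to
a fixed point could walk away from the crowd's centre on pathological
inputs, and one pass already removes the isolated-error mode the cutoff
targets. If every mask would be excluded, all are kept and the result is
flagged rather than returning an empty consensus.

`extract_consensus_contours()` inverts rasterization for vector export: it
collects the boundary (crack) edges of the mask on the pixel-corner lattice
and links them into closed loops. Any pairing at degree-4 corners yields
loops whose even-odd (XOR) combination reproduces the mask *exactly* —
crossing parity depends only on the edge multiset — which the suite checks
on random masks with holes.

## Volume assembly

Marks map back as `(x, y, z) = (x_subject + u, y_subject + v,
z_subject + (frame - annotation_frame) * z_stride)`; marks landing in
padding are flagged and excluded. Detections found independently in
overlapping tiles are merged by clustering with `min_samples = 1` at a
merge radius (default: the aggregation `eps`); each merged detection takes
the support-weighted mean centroid, summed support, and the support-weighted
majority label. Per-subject agreement rasters are fused per voxel by the
*mean* of covering tiles' agreements, thresholded at 0.5 — preserving the
"half or more" semantics across tiles; a coverage-weighted alternative was
left aside because uniform meaning across the volume is easier to reason
about and audit. Voxels covered by no tile stay unset.

## The simulator

`make_phantom()` renders spherical bright blobs (sigmoid intensity
fall-off, width 0.8 px) on a noisy background (Gaussian, default sd 0.03
around 0.2), packed by rejection sampling so objects never touch each other
or the boundary. Ground truth per object: centroid, radius, label, and a
per-slice boundary polygon — the sphere's cross-section at each slice's
centre plane, sampled at roughly one vertex per 1.5 px of circumference,
matching the near-continuous traces freehand tools record. Cross-sections
narrower than 1.5 px in radius are not emitted (no volunteer can outline a
three-pixel speck), which slightly truncates the poles of the truth masks.

The volunteer model (`volunteer_model()`) has six parameters: the number of
volunteers (default 5, a typical per-subject retirement scale), radial
contour jitter (default sd 1 px), point jitter (default 1 px in x and y,
half in z), a spam rate (fraction of annotations replaced by off-structure
scribbles or spurious marks; spam strokes are deliberately *open* polylines
to exercise closure rejection), a miss rate, and an answer accuracy. Every
draw comes from a stream keyed by `(seed, volunteer, subject)`, so adding a
volunteer never perturbs existing ones and all runs replay bit-identically.

What the simulator does *not* model: realistic EM texture, correlated
hand-tremor along a stroke (jitter is independent per vertex), volunteer
learning over time, and systematic inter-volunteer bias (e.g. everyone
outlining slightly outside a membrane). Passing recovery tests therefore
demonstrate that aggregation recovers truth under unbiased, independent
noise and spam — not that any real crowd is unbiased.

## Problem scales for the recovery experiments

The recovery experiments run at two deliberate scales:

* **Point studies** use particle-scale phantoms (radius 6–9 px in
  96×96×24 volumes, 3 objects) — the scale at which marking centres is the
  natural task.
* **Contour studies** use cell-scale structures (radius 10–14 px, one to
  two objects in 96×96×36 volumes, FOV cropped around each structure) —
  the scale at which outlining is the natural task. The scale is not
  arbitrary: with vertex jitter sd `s` and `n` volunteers, the consensus
  boundary sits about `0.4 s` off the truth on average (the median of `n`
  independent offsets), so the achievable IoU is roughly
  `1 - 2 * 0.4 * s * P / A` for perimeter `P` and area `A`. At `s = 1` and
  a 6 px radius that ceiling is ~0.88; outline-scale structures
  (`r >= 10 px`) are where sub-pixel-accurate consensus (IoU > 0.9) is
  attainable at all.

Under those conditions the suite asserts, over fixed seeds: clean contour
consensus IoU > 0.9 (20 seeds); with one-in-five spam and outlier removal,
IoU > 0.85; point aggregation recovers every object with centroid error
< 1.5 px and no spurious detections at 20% spurious marks (20 seeds); and
full end-to-end reassembly reaches volume-mask IoU > 0.85 (10 seeds).
The centroid bound is ~3.3 standard deviations of the five-mark mean, so
a rare miss under fresh seeds is expected statistical behaviour, not a
pipeline failure.

## Numerical and degenerate-input choices

* Constant volumes stretch to all-zero rather than dividing by zero.
* Partial binning blocks average over their actual size (field of view is
  preserved); binning never truncates.
* TIFF volumes store 16-bit samples; the 8-bit grid embeds exactly
  (65535 = 255 × 257), so data read from 8-bit files round-trips
  bit-exactly. Arbitrary doubles are quantised round-half-up.
* Empty-vs-empty mask comparisons define IoU = Dice = 1 (perfect
  agreement about nothing).
* DBSCAN neighbourhoods are inclusive (`<= eps`) and count the point
  itself, so `min_samples = 1` makes every point a core point and nothing
  noise — which is exactly what detection merging wants.
* All tie-breaks (vote ties, identical timestamps, equal label support)
  resolve lexicographically and are flagged where a flag is meaningful.

## Known limitations

Orthogonal-slice subjects (a route to recovering the stack-end and
missing-wedge losses) are not generated. Stacked or touching objects are
not disambiguated beyond the label-vote cleaning pass. Contour consensus is
strictly per-slice; no 3D surface regularisation links adjacent planes.
Annotator-skill weighting is out of scope — every volunteer's vote counts
equally.
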