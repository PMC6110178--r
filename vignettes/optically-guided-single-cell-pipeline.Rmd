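---
title: "Methods: optically guided single-cell sampling and spectral classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optically guided single-cell sampling and spectral classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmdpipe)
```

# Scope and model of the system

`lmdpipe` models the computational side of an automated platform that
recognizes individual cells in bright-field microscope images, excises or
ablates them with a UV laser, captures the material into a liquid-vortex
probe coupled to an electrospray TOF mass spectrometer, and classifies each
cell from its lipid and pigment mass spectrum. Everything the physical
instrument does — stage motion, laser firing, probe fluidics, ionization —
is out of scope; everything that turns pixels and scans into decisions is
implemented and testable here.

Two sampling regimes are modelled, matching the two model systems the
platform was designed around:

* **Interior raster ablation** for spatially connected tissue (onion
  epidermis, elongated cells of roughly 100–150 µm): the laser fills the
  inside of each cell boundary so neighbouring cells are not disturbed.
* **Cut-and-drop (CnD) microdissection** for dispersed cells on a 4 µm PEN
  membrane (algae of roughly 10 µm): the laser cuts a closed contour
  around the cell through the membrane, after a puncture shot at the
  cell's centre of weight (so osmotically resistant cell walls are opened
  before solvent capture), and a final shot ejects the cut disc into the
  probe.

# Cell recognition

Segmentation assumes dark, roughly convex cells on a brighter flat
background, the contrast regime of pigmented cells in bright-field. The
fixed algorithm is: optional median-filter background flattening, global
Otsu threshold, morphological opening with a disc whose radius is 20% of
the smallest expected cell radius (at least 1 px), hole filling,
connected-component labelling, optional distance-map watershed for
touching cells (off by default), and polygonization of each component's
outer contour. Contours run through boundary-pixel centres, are simplified
with a 0.5 px Douglas–Peucker tolerance, and then dilated outward by half
a pixel so the polygon tracks pixel edges; without that half-pixel step a
10 px-radius cell loses about 10% of its area, with it the bias is within
a few percent.

Conventions that must be fixed for downstream geometry (and are, package
wide): stage frame in micrometres, x right / y down aligned with pixel
axes; continuous 0-based pixel coordinates with the centre of pixel
(row i, col j) at (j + 0.5, i + 0.5) pixels; polygons stored
counter-clockwise (positive shoelace area); cells reported sorted by
(y, x) centroid so output order is deterministic. Components touching the
image border are discarded — their boundaries are incomplete and the real
platform samples only fully visible cells. Connected components are
4-connected (the EBImage labeller); after disc opening, diagonal-only
pixel bridges do not survive, so the distinction from 8-connectivity is
immaterial here. Background flattening is available
(`background_radius`) but off by default: the synthetic scenes have flat
backgrounds, and flattening a field of 150 µm cells would need median
windows larger than is useful.

Recognition presets encode the two regimes: `algae` keeps 20–700 µm² at
circularity ≥ 0.5; `onion` keeps 2,000–10⁶ µm² at circularity ≥ 0.2
(elongated cells score low on 4πA/P²).

**Isolation filter.** CnD sampling is only single-cell if the excised area
contains no neighbour. A cell is kept iff no other cell's polygon comes
within the cut margin of its own polygon — implemented as an exact
polygon–polygon minimum-distance test, which is equivalent to intersecting
the round-join dilation. The filter is deliberately symmetric (both
members of a close pair are dropped) and monotone in the margin.

# Path planning

**Raster mode** produces an outline-plus-hatch toolpath over the cell
polygon inset inward by `inset` (default 2 µm — the stand-off that keeps
ablation away from shared cell walls): one perimeter pass along the inset
ring, then horizontal scan segments at `y = y_min + k · spacing` clipped
to the inset region, linked in serpentine order, with one closing line at
the region's top edge whenever the remainder gap exceeds half the
spacing. `spacing` defaults to 5 µm, a typical laser spot diameter. The
perimeter pass and closing line exist because parallel hatching alone
leaves uncovered slivers along boundary stretches that run obliquely
between two scan lines — on rotated ellipses these slivers measure about
2% of the inset area at 5 µm spacing, and the package's coverage contract
(≥ 99% of the inset region within spacing/2 of the path) would fail
without them. Cells whose inset region is empty (thinner than twice the
inset) raise an explicit "too small to raster" error.

**CnD mode** offsets the cell polygon outward by `margin` (default 3 µm
for ~10 µm algae) using round-join polygon buffering with 16 arc segments
per quadrant — round joins keep the clearance constant and avoid miter
spikes at sharp vertices. If the offset produces multiple rings, the
largest is used. The loop is repeated `n_passes` times (default 2, enough
for a 4 µm PEN membrane) and closed; puncture and eject points are the
polygon's area centroid, replaced by the nearest interior point for
non-convex cells whose centroid falls outside.

Paths are ordered by a greedy nearest-neighbour tour over their anchor
points with ties broken by cell id — deterministic, and never worse than
visiting cells in id order.

# MS processing

One TOF scan covers m/z 700–1000 with 0.05 s accumulation. Processing a
timed run into per-cell features proceeds as:

1. **Chronogram**: total ion current per scan, in time order.
2. **Event detection**: maximal runs of scans with
   TIC > median + `k_mad` · MAD (default `k_mad` = 5); runs closer than
   `min_gap` (default 1 s) are merged, so distinct cells remain
   resolvable up to roughly one cell per second. Each event window is
   widened by half a scan period per side so single-scan events still
   have a well-ordered window around their apex.
3. **Extraction**: scans inside the window are **summed**, not averaged —
   summing preserves ion counts for weak single-cell signals — and the
   per-channel median of all out-of-event scans is subtracted as
   baseline, floored at zero.
4. **Recalibration**: each lock mass is matched to the nearest observed
   peak centroid within `tolerance` (default 0.1 m/z); with ≥ 2 matches
   the observed→reference map is fit as a first-degree polynomial by
   least squares, with exactly 1 as a constant offset, and applied to the
   whole axis; with 0 matches the spectrum is returned unchanged but
   flagged. The default lock masses are the three protonated pigments
   present in every algal spectrum — chlorophyll a, chlorophyll b,
   pyropheophytin a — computed from their elemental formulas, never
   hard-coded. Peak centroids come from three-point Gaussian
   (log-parabola) interpolation at each local maximum, which is exact for
   sampled Gaussian peaks; a windowed intensity-weighted mean (the
   fallback) carries a bias of order 10⁻⁴ m/z from window asymmetry,
   enough to corrupt the fitted slope.
5. **Binning**: intensities are summed into 3,000 half-open bins
   [700.0 + 0.1·i, 700.0 + 0.1·(i+1)), i = 0…2999 — lower edge
   inclusive, floor indexing, m/z ≥ 1000 excluded — then divided by the
   grand total (total-ion normalization; the choice of normalization is
   the standard one for spectral classification and is isolated behind
   `normalize = TRUE`). An all-zero spectrum stays all-zero and
   unnormalized. The bin index adds 10⁻⁹ bin widths (10⁻¹⁰ m/z) before
   the floor so masses sitting exactly on a bin edge — as when re-binning
   an already binned grid — are not pushed down a bin by floating-point
   representation; binning is then exactly conservative, order-invariant
   and idempotent.

# Classification

The classifier is PCA-LDA. PCA is an SVD of the column-mean-centred
feature matrix with no variance scaling — after total-ion normalization
all spectra share a scale, and scaling 3,000 mostly-empty bins would
amplify noise. Loadings are sign-fixed (largest-magnitude element
positive) for determinism. `k = 2` components by default; additional
components add little captured variance for two-class lipid profiles and
`k` is configurable.

The discriminant is Fisher's: w ∝ S_w⁻¹(μ₁ − μ₂) with pooled within-class
covariance (equal priors, shared covariance — the 50/50 training design),
threshold at the midpoint of the projected class means, classes in
alphabetical order with the first class on the positive side, ties at the
threshold assigned to the alphabetically first class. A ridge of
10⁻⁸ · mean(diag(S_w)) is added only when S_w is near-singular
(rcond < 10⁻¹²).

Leave-one-out cross-validation refits the **whole** model — PCA mean,
loadings and the discriminant — inside every fold, so no information
about the held-out cell leaks into the projection. The cheaper variant
that fixes PCA on the full data is available (`refit_pca = FALSE`) but is
mildly optimistic and not the default. Apportionment of a test set uses
the training mean, loadings and threshold unchanged.

# The synthetic-data generators

The generators define the study conditions the package is tested under:

* **Images**: ellipses of the ~10 µm algal size regime (major semi-axis
  4–6 µm) or arbitrary user-specified geometry, rendered dark
  (intensity 0.35) on a bright background (0.85) with additive Gaussian
  pixel noise; an image SNR of 10 corresponds to noise sd 0.05 on that
  0.5 contrast. Overlapping or frame-clipping placements are rejected
  unless explicitly allowed.
* **Spectra**: Gaussian peaks (FWHM 0.05 m/z, about five grid steps at
  the default 0.01 m/z grid) at the species profile's ion centroids, each
  integrating to `total_intensity · abundance` counts (default total
  10⁴), plus per-channel Gaussian noise floored at zero. The default
  profiles encode the two algal classes: Euglena gracilis with 34:7 and
  36:7 MGDG, 34:4 DGDG and 30:8 PC; Phacus with 34:6 and 36:8 MGDG and
  30:9 PC; both with protonated chlorophyll a, chlorophyll b and
  pyropheophytin a, chlorophyll b more abundant in Phacus. All m/z are
  derived from elemental formulas at load time; lipids are simulated as
  [M+NH₄]⁺ adducts (their usual positive-ESI form — note the short
  highly unsaturated PCs would fall below m/z 700 as [M+H]⁺), pigments
  as [M+H]⁺. Relative abundances are free parameters of the simulation
  with documented defaults; no absolute single-cell intensities are
  published to anchor them.
* **Runs**: scans every 0.05 s at a flat per-channel baseline, with each
  cell event carried under a Gaussian time envelope of sigma = 2 scan
  periods (wide enough that windowed extraction is meaningfully tested),
  unit weight at the apex. Events must be separated by more than one
  burst width.
* **Experiments**: `simulate_experiment()` builds a jittered-grid slide
  (40 µm pitch keeps every cell isolated by construction), recognizes and
  plans it exactly as the pipeline would, and synthesizes the run in
  planned sampling order — so a subsequent `run_pipeline()` call pairs
  events to cells correctly and can be scored against the returned truth
  table. Co-capture contamination (a previously cut cell of the other
  class released together with the sampled one) is modelled by
  `contaminate()`: an intensity-wise convex combination of two spectra on
  one grid.

All randomness flows from one explicit seed per generator call through a
local RNG scope, so every artifact is bit-reproducible and the caller's
RNG state is never touched.

What the generators do **not** emulate: optical point-spread and defocus,
chloroplast substructure, isotope envelopes, chromatographic or
matrix effects, electrospray suppression, irregular (animal) cell shapes
and overlapping cells. Passing tests therefore demonstrate the
correctness of the computational chain under idealized contrast and peak
shapes, not recognition or classification performance on real
instrument data.

# Problem sizes

The classification experiments are simulated at the study design sizes:
50 + 50 unmixed training cells and a 60 + 40 mixed test set with two
contaminated cells, on the full 0.01 m/z grid. End-to-end pipeline runs in
the test suite use a handful of cells, a 0.02 m/z scan grid and a 2 s
inter-cell dwell: a timed run is held in memory as dense profile scans,
and these sizes keep a full simulate–recognize–plan–extract–classify cycle
in seconds while exercising every code path. `simulate_experiment()`
itself defaults to the study conditions (50/50 cells, 0.05 s scans, 10 s
dwell, 0.01 m/z grid); users scaling the run length up should scale the
scan grid step accordingly.

# Known limitations

* Segmentation resolves no overlapping cells (watershed splitting is
  available but off by default) and assumes near-elliptical shapes of a
  common size regime per run.
* The raster planner uses parallel hatching with an outline pass;
  concentric-contour filling is not implemented.
* Inward polygon offsets of strongly non-convex cells may split the inset
  region; only the largest component is rastered.
* Event-to-cell pairing assumes events arrive in planned sampling order;
  dropped or spurious events shift the pairing and are only reported, not
  repaired.
* The m/z axis of extracted spectra inherits the scan grid; recalibration
  shifts the axis continuously but does not resample it.
* LDA is strictly two-class, with equal priors and a shared covariance.
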