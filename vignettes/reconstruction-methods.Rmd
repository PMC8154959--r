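---
title: "Reconstructing the embryonic palate and tongue in 3D from serial sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the embryonic palate and tongue in 3D from serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palate3D)
```

## The problem

Secondary palate development in the mouse hinges on a rapid event around
embryonic day 13.5: the paired palatal shelves reorient from a vertical
position flanking the tongue to a horizontal position above it. Because
the event is fast and the palate is hidden inside the oral cavity, it is
mostly studied through serial H&E histology — hundreds of 7 µm coronal
sections per head. A single section shows only a plane; understanding the
spatial interaction between shelves and tongue requires reassembling the
section series into a 3D model.

`palate3D` implements that reassembly as a deterministic, testable
pipeline: per-slice segmentation of the oral-cavity region, rigid
slice-to-slice alignment, anisotropic voxel volume assembly with volume
measurement, and iso-surface meshing with cleanup and STL/PLY export. A
synthetic phantom generator produces section stacks of exactly known 3D
geometry so that every stage — and the pipeline end to end — can be
validated against ground truth without any real tissue.

## Segmentation model

H&E-stained tissue absorbs strongly in the green band, so in the green
channel of a brightfield photograph tissue is dark and the unstained
cavity lumen bright. The per-slice segmentation is deliberately simple
and parameter-light:

1. **Green channel** (`greenChannel`): intensities scaled to [0, 1]; red
   and blue are discarded (tests assert they can be scrambled without
   changing any output).
2. **Mean filter** (`meanFilter`, window 15): each pixel becomes the
   arithmetic mean of its 15 × 15 neighborhood (225 source pixels).
   Borders are handled by edge replication — zero padding would darken
   the frame margin and carve false cavity boundaries at the ROI edge.
3. **Fixed threshold** (`binarize`, 0.5): foreground is strictly greater
   than 0.5 on the normalised scale. Since 8-bit data normalised by 255
   cannot equal 0.5 exactly, strict versus non-strict comparison only
   matters for synthetic inputs; strict is documented and tested. An
   `invert` flag covers stains with opposite polarity.
4. **8-connected components** (`labelComponents`): the labeling is
   authored in C++ (two-pass union-find) and checked against a
   flood-fill oracle on all 512 3 × 3 masks and 1000 random 8 × 8
   masks.
5. **Largest component** (`largestComponent`): the largest bright
   component is taken as the oral cavity. Area ties (which real data
   never meets but tests do) are broken by the component whose first
   pixel comes earliest in raster-scan order — deterministic and
   independent of label numbering. A floor `min_area_px` (default 64)
   prevents a noise speck from defining the cavity on a near-empty
   slice; such slices are flagged *degenerate* and carried through the
   pipeline rather than raising errors, because real serial series
   contain damaged sections.

The fixed 0.5 threshold presumes reasonably normalised exposure; the
filter window is specified in pixels, so on very coarse rasters (or
heavily downsampled data) the window becomes large relative to the
anatomy and erodes convex corners — the phantom suite quantifies this
(see *Validation* below).

## Rigid alignment

Serial sections land on slides with arbitrary in-plane offset and
rotation, so masks must be rigidly registered before stacking. The
registration (`estimateRigid`) is intensity-free, operating on the
cavity masks:

* **Initialisation.** Translation from the centroid difference;
  rotation from the difference of second-moment principal-axis angles.
  Second moments cannot distinguish an angle from its π-complement, so
  both candidates are scored and the better kept.
* **Refinement.** Coordinate descent maximising a *soft Dice* overlap:
  both masks are first passed through a 3 × 3 box filter, turning hard
  1-px edges into linear ramps, and the moving field is bilinearly
  resampled. This makes the objective smooth in (θ, t) and lets its
  maximum localise the pose to a fraction of a pixel/degree — binary
  nearest-neighbor overlap is piecewise constant and an order of
  magnitude noisier. Two rounds of a fine θ grid (±5° at 0.1°, then
  ±0.3° at 0.02°) and a local translation search; grid ties prefer the
  smallest change, so self-registration returns the exact identity.

`alignStack` estimates transforms between consecutive non-degenerate
slices and composes them outward from a reference slice — the middle of
the stack by default, halving worst-case drift relative to anchoring at
slice 1. Degenerate slices inherit the composed transform of their
nearest good neighbor. Chaining neighbors rather than registering every
slice to one template is deliberate: real anatomy changes along the
series, so only adjacent sections can be assumed to share a silhouette.

The transform convention is stated once and tested by a closed-form 90°
case: `T(p) = R(θ)(p − c) + c + t` on 1-based `(row, col)` pixel
coordinates, row 1 at the top, θ counter-clockwise in (row, col) algebra
(visually clockwise). `maxRotDeg` bounds the rotation search (default
10°); note that with per-slice jitter of σ = 3° the *relative* rotation
of a consecutive pair occasionally exceeds 10°, so the phantom
validation calls the aligner with a wider bound (25°).

## Volume and surface

`assembleVolume` stacks the aligned masks into a labeled voxel grid with
anisotropic spacing `(pixel, pixel, section)` in µm — 7 µm sections
versus finer in-plane sampling are honoured as such, never resampled to
isotropic voxels, which avoids interpolation artifacts. Degenerate
planes are filled by copying the nearest good plane (ties to the earlier
one). `measureVolume` is voxel counting times the anisotropic voxel
volume; it is additive over labels and invariant to axis permutation
(with correspondingly permuted spacing).

`extractSurface` triangulates the 0.5 iso-level of a label's indicator
field, sampled at voxel centers and padded with background so interior
structures produce watertight meshes. The triangulation is **marching
tetrahedra** on the Freudenthal six-tetrahedra cube decomposition,
which is face-to-face consistent across cubes and therefore crack-free
by construction; vertices are scaled by the voxel spacing into µm and
faces wound outward (positive signed volume). On a single positive
voxel this yields a closed solid of volume 0.5 voxel; on a 10³ cuboid
the enclosed volume is within 1% of the voxel count, and the error
decreases monotonically as resolution doubles (tested across three
resolutions).

Two cleanup steps replace the interactive operations a commercial mesh
studio would offer, with explicit, deterministic algorithms:

* `removeSpikes`: a vertex whose distance to the centroid of its 1-ring
  neighbors exceeds `median + 3·IQR` of that statistic is snapped onto
  the centroid; topology unchanged; meshes under 5 vertices untouched.
* `smoothMesh`: Taubin two-step smoothing, λ = 0.5 then µ = −0.53, 10
  iterations by default. The alternating shrink/inflate pair suppresses
  surface noise with almost no net shrinkage: on a sphere with 5% radial
  noise, 10 iterations cut the RMS radial deviation by well over half
  while changing the enclosed volume by under 2%.

Export is binary STL (geometry only, the CAD interchange default) and
ASCII PLY carrying the structure's display color as per-vertex RGB —
palatal shelves orange, tongue pink, other structures gray, resolved via
`grDevices::col2rgb`. STL round-trips to float32 precision.

Separating the cavity into named substructures (tongue versus shelves)
from image intensity alone is out of scope: on real data that
distinction was always a manual curation step, so the pipeline
reconstructs the single cavity label, and phantom ground truth carries
substructure labels for validation.

## The phantom: what it emulates, and what it does not

`embryoPreset` builds two scenes on a 1750 × 3500 µm coronal frame:

* **pre-elevation** (152 sections at full scale): a midline tongue body
  (elliptical cross-section, 340 × 550 µm semi-axes) flanked by two
  vertical shelf slabs, each overlapping the tongue's lateral edge so
  the bright union is one connected component on every slice;
* **elevating** (250 sections): the tongue shifted laterally, one shelf
  already horizontal above it, the other still vertical — the
  asymmetric, laterally deviated configuration seen mid-elevation.

Rendering (`renderStack`) writes the scene into the green channel
(cavity level 0.8 on tissue level 0.2 — symmetric about the 0.5
threshold, so mean filtering introduces no net boundary bias), adds
seeded Gaussian intensity noise (σ = 0.05, clipped), and displaces each
slice by a seeded random rigid jitter (σ = 5 px translation, 3°
rotation) about the frame center, recorded exactly in the ground truth.
Red/blue channels mimic the pink H&E hue and are cosmetic. The class
separation is kept ≥ 3 noise standard deviations by construction
(enforced by the `PhantomSpec` validity method), so the fixed threshold always
falls between the class means. Gaussian noise was chosen over Poisson
because it keeps that separability guarantee analytic.

Design choices worth stating explicitly:

* **Primitives are extruded (z-uniform).** Consecutive phantom slices
  have identical silhouettes up to jitter, which is exactly the
  assumption slice-to-slice registration rests on; it also makes the
  recorded jitters the literal ground truth that `alignStack` must
  invert, so pose-recovery tests are exact by construction. Real series
  taper and remodel along the axis; the phantom deliberately does not
  model that, so passing the recovery test says the aligner inverts
  rigid displacement, not that it tracks anatomical change.
* **The bright region is the tongue ∪ shelves union.** In real H&E the
  bright lumen *surrounds* the dark tissue; the phantom simplifies by
  letting the labeled solids themselves be the bright "cavity region".
  The segmentation pipeline is agnostic to this — it recovers the
  largest bright component either way.
* **Size factor.** `sizeFactor` scales raster and slice count down while
  scaling pixel size and thickness up, leaving all µm geometry and
  ground-truth volumes unchanged. The validation suite runs at 0.12
  (120 × 240 px, 30 slices, ~15 µm pixels): the smallest scale at which
  the fixed 15-px filter window stays small relative to the anatomy.
  At coarser scales the window's convex-corner erosion grows (≈ −3.6%
  cavity area at factor 0.10, ≈ −2.5% at 0.12, vanishing toward full
  scale); this is a property of the fixed-window method itself, which
  the phantom makes measurable.
* Sectioning tears, folds, stain batch variation, and photorealistic
  texture are not modeled.

## Validation results the suite computes

The acceptance suite (and `scripts/acceptance.R`) recomputes, from
scratch, per run: component labeling against the flood-fill oracle;
pose recovery on 10 seeded jittered stacks (mean residual ≤ 1 px, ≤ 1°;
typical values ≈ 0.2–0.4° and ≈ 0.2 px, with translation residual
measured as the displacement at the frame center); end-to-end cavity
volume within 5% of ground truth (typically ≈ 2.5% at size factor
0.12, dominated by the filter-window bias above); mesh versus voxel
volume agreement within 5% (typically < 0.1%); and bit-identical
artifact checksums across repeated pipeline runs.

## Degenerate inputs and numerical conventions

* Empty or sub-floor slices: degenerate masks, interpolated over during
  assembly; an all-degenerate stack is an error.
* Area ties in component selection: raster-scan-order tie-break.
* Thresholding: strictly `> 0.5` after [0, 1] normalisation.
* Pixel size has **no default**: image files do not carry it, and a
  guessed value would silently corrupt every µm³ measurement. It is a
  required configuration input; phantoms define theirs.
* File ordering: manifest or lexicographic zero-padded names — never
  timestamps.
* All randomness (phantom noise and jitter) derives from an explicit
  integer seed; the RNG state of the calling session is saved and
  restored.

## Configuration and entry points

`runPipeline` drives the whole chain from a config list or YAML file
(`readPipelineConfig`), writing per-slice QC, the transform table, the
volume report, meshes, and a manifest with MD5 checksums of every
artifact. Defaults follow the method's standard values: window 15,
threshold 0.5, 8-connectivity, 7 µm sections. A thin command-line
wrapper ships in `inst/cli/palate3d.R` with verbs `run`, `phantom`, and
`qc`, and exit codes 0/2/3/4 (success / config error / data error /
stage failure).
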