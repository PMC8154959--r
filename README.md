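# palate3D

3D reconstruction of the embryonic palatal shelves and tongue from
serial histological sections.

## The problem

Around embryonic day 13.5 the mouse secondary palate performs a fast,
hidden maneuver: the paired palatal shelves reorient from vertical
(flanking the tongue) to horizontal (above it) before fusing. Most of
what is known about this process comes from serial H&E histology —
hundreds of 7 µm coronal sections per embryo head — but single sections
show only planes. `palate3D` rebuilds the section series into measurable
3D surface models, for developmental biologists studying palatogenesis
(and, more generally, anyone reconstructing a small tissue block from
ordered 2D brightfield sections).

## The method

For a stack of RGB section photographs, per slice:

1. greyscale via the **green channel** (H&E tissue is dark in green, the
   cavity lumen bright), intensities in [0, 1];
2. **15 × 15 mean filter** (each pixel replaced by the average of the
   225 pixels around it, edges replicated);
3. **threshold at 0.5**: the bright side is foreground;
4. **8-connected component labeling**; the largest component is the
   oral-cavity region of that slice (Dice-validated against phantom
   ground truth).

The per-slice cavity masks are then **rigidly registered** — translation
initialised from centroids, rotation from second-moment principal axes,
refined by maximising a smooth (soft) Dice overlap — and composed
outward from the middle reference slice. The aligned masks become an
anisotropic labeled voxel volume (µm in-plane × 7 µm sections), from
which the package measures structure volumes (voxel count × voxel
volume) and extracts watertight triangle meshes (marching tetrahedra at
the 0.5 iso-level), cleans spikes (1-ring outlier snap at median +
3·IQR), smooths (Taubin λ = 0.5, µ = −0.53), and exports STL and
color-carrying PLY (shelves orange, tongue pink).

Because real tissue carries no ground truth, the package ships a
**phantom generator**: synthetic section stacks of exactly known
geometry (a tongue body and two shelf slabs in a bright cavity region),
with seeded per-slice rigid jitter and Gaussian noise. Every pipeline
stage is tested against the phantom truth; see the methods vignette
(`vignettes/reconstruction-methods.Rmd`) for the model, parameter, and
validation details.

## Worked example

Reconstruct a mid-elevation phantom (scaled to desk size) and compare
against its ground truth:

```r
library(palate3D)

spec  <- embryoPreset("elevating", sizeFactor = 0.12, seed = 42)
truth <- buildTruth(spec)
stack <- renderStack(truth, spec)
stack
#> SectionStack: 30 slices of 120 x 240 px, 14.6 um/px, 58.3 um sections

masks   <- segmentStack(stack)
masks[[15]]
#> CavityMask (slice 15): 3234 px (6.878e+05 um^2), centroid (56.4, 108.2)

aligned <- alignStack(masks, thickness = sectionThickness(stack),
                      maxRotDeg = 25)
vol     <- assembleVolume(aligned)
volumeReport(vol)
#>   label voxels volume_um3
#> 1     1  97073 1204283818

measureVolume(truth@volume, 1:4)   # ground truth
#> [1] 1234889323

mesh <- smoothMesh(removeSpikes(extractSurface(vol, 1L)), 10)
mesh
#> SurfaceMesh (label 1, gray): 57010 vertices, 114016 faces
meshVolume(mesh)
#> [1] 1203786542
exportMesh(mesh, "cavity.stl")
```

The reconstructed cavity volume (1.204 × 10⁹ µm³) lands within 2.5% of
the ground truth (1.235 × 10⁹ µm³) despite per-slice jitter of σ = 5 px
and 3°; the mesh volume agrees with the voxel count to < 0.1%. The
deviation-direction summary used for cohort statistics:

```r
lateralDeviationStats(7, 8)
#>   direction n  percent
#> 1      left 7 46.66667
#> 2     right 8 53.33333
```

Whole runs are driven by a YAML config (`runPipeline`) or the CLI
wrapper:

```sh
Rscript inst/cli/palate3d.R phantom --stage elevating --seed 7 --out phantom_out
Rscript inst/cli/palate3d.R run -c config.yaml -o results_dir
```

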