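---
title: "Histology-based 3D reconstruction and invasion-front morphometry with tumor3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histology-based 3D reconstruction and invasion-front morphometry with tumor3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumor3d)
```

## The measurement problem

Early-stage oral tongue squamous cell carcinoma (OTSCC) is routinely graded
from two-dimensional sections, but invasion is a three-dimensional process:
an apparently isolated island of cancer cells on a slide may be a
cross-section of a cord that is connected to the main tumor out of plane.
`tumor3d` implements a serial-section reconstruction pipeline for 3-mm
tissue cores punched from the deep invasion front: consecutive 4-µm
sections are double immunostained (pan-cytokeratin with a DAB brown
chromogen marking carcinoma cytoplasm; Ki67 with Vector SG blue-gray
marking proliferating nuclei), digitized at 0.92 µm/pixel, rigidly aligned,
colour-deconvolved, assembled into an anisotropic voxel volume, and
measured.

The quantities of interest per case are:

* total reconstructed tissue volume $V_{total}$ (core disk area × stack
  height), tumor parenchyma volume $V_p$ and stroma volume
  $V_{total} - V_p$;
* parenchymal–stromal border area $S$ and the shape-complexity index
  $S/V_p$ (mm$^{-1}$);
* Ki67$^+$ nucleus counts in parenchyma and their density ($\times 10^4$
  /mm$^3$ of $V_p$);
* discohesive cancer foci: cancer cells or clumps fully detached from the
  main mass and completely surrounded by stroma in 3D — their count,
  volume fraction of $V_p$, equivalent sphere diameters
  $d = (6V/\pi)^{1/3}$ binned into size classes, and per-focus
  Ki67$^+$/Ki67$^-$ nucleus counts.

Because the original image stacks are not publicly available, the package
also ships a synthetic phantom generator that emulates the acquisition
end-to-end, so every stage is validated by parameter recovery against a
known voxel truth, and a bundled reference 14-case morphometry series
(`reference_cases()`, `reference_focus_sizes()`) against which all derived
statistics are recomputed.

## Pipeline stages and their models

### Rigid registration

Sections land on the glass with independent shifts and small rotations.
Alignment is strictly rigid — translation plus rotation, never scaling or
shear — because affine or deformable warps let per-slice distortions
accumulate through a stack and degrade the reconstruction. `estimate_rigid()`
is a "rough and fine" estimator:

1. **Rough**: candidate rotations are scanned on a block-averaged pyramid
   level, with the translation at each angle obtained by Fourier
   cross-correlation.
2. **Fine (intensity)**: Nelder–Mead refinement of $(t_x, t_y, \theta)$
   maximizing normalized cross-correlation of luminance at full resolution.
3. **Fine (correspondence)**: the correlation optimum is measurably biased
   by genuine structural change between consecutive sections (cords and
   projections drift laterally with depth). Nuclei, in contrast, are
   point-like markers that recur at identical in-plane positions on the
   2–3 sections their 7-µm sphere spans. Centroids of small compact blobs
   — dark luminance objects and, for RGB input, footprints in the unmixed
   SG channel, intensity-weighted for sub-pixel precision — are matched
   mutually-nearest-neighbour within a shrinking gate (2.5, 1.5, 1.2 px)
   and a closed-form rigid Procrustes fit replaces the correlation
   estimate. Elongated blobs are rejected by a compactness filter, since
   oblique cuts of cords drift from section to section and would
   re-introduce the bias; with fewer than 4 matches only the (well-posed)
   translation correction is applied.

`register_stack()` composes neighbour transforms outward from the middle
slice (halving worst-case accumulation versus first-slice anchoring; the
reference-slice convention is this package's choice) and then re-anchors
each newly placed slice by a translation-only Procrustes match against the
nucleus anchor map of the two previously placed slices mapped into the
reference frame — because nuclei span 2–3 sections this adds lag-2 ties
that a plain chain lacks, suppressing random-walk drift. A final symmetric
sweep re-anchors every slice against both neighbours. Each slice is
resampled exactly once (bilinear for intensities, nearest-neighbour for
masks).

On phantoms with seeded misalignments up to 10 px / 3°, composed
transforms are recovered within 1 px / 0.5° per slice over a 40-slice
stack (the tests measure ≈0.2–0.4 px and ≈0.2–0.3°), and registering an
already-aligned stack moves no slice by more than 0.5 px / 0.25°.

### Stain separation

Brightfield chromogens follow Beer–Lambert: per channel
$I_c = I_{0,c}\,10^{-\mathrm{OD}_c}$ with
$\mathrm{OD} = c_{DAB}\,v_{DAB} + c_{SG}\,v_{SG}$, where the $v$ are unit
optical-density vectors. `rgb_to_od()` inverts this (with a one-quantum
floor and clamping at zero) and `unmix()` solves the 3×3 system per pixel
(Ruifrok–Johnston colour deconvolution), clamping negative concentrations.
The DAB vector is the published Ruifrok–Johnston one; SG has no canonical
published vector, so the default is the normalized blue-gray direction
(0.60, 0.55, 0.58) with an orthogonal residual row — only
rendering/unmixing self-consistency depends on this choice, and the
round-trip test pins it (machine precision without noise).

Segmentation uses a **single pooled Otsu threshold** per stack and channel
(histogram of all in-core pixel values over all slices): per-slice
thresholds would flicker from section to section and corrupt 3D
continuity; a per-slice policy remains available. In-plane objects smaller
than a 2-µm-radius disk are removed as sub-nuclear specks. Holes in the
parenchyma mask are deliberately **not** filled: Ki67$^-$ nuclei are
defined as open, unstained spaces fully circumscribed by CK$^+$ cytoplasm,
and `detect_negative_nuclei()` extracts exactly those in-plane background
components (4-connectivity, not reaching the slice border) with areas of
10–150 µm². Stroma is tissue minus parenchyma, by exact voxel subtraction.

### Volume assembly and the two-slice nucleus filter

Slices stack with no z-resampling: voxels are 0.92 × 0.92 × 4 µm. The
analyzed field is the core cylinder; $V_{total}$ is disk area × stack
height. Foreground uses 8-connectivity in-plane and 26-connectivity in 3D,
backgrounds the complementary 4/6 pairing.

Candidate nucleus voxels are grouped into 26-connected 3D objects and
**every object confined to a single section is deleted as noise**; a true
nucleus must appear on at least two consecutive sections. Survivors are
assigned to parenchyma or stroma by majority voxel overlap with the
parenchyma volume (ties to parenchyma, the intended assignment for nuclei
inside CK$^+$ cytoplasm). Hole-derived Ki67$^-$ candidates are by
definition inside cytoplasm, so they bypass the vote
(`compartment = "parenchyma"`): a majority vote against the parenchyma
mask would classify every hole as stroma.

### Discohesive foci

`partition_components()` labels the 26-connected components of the in-core
parenchyma and classifies them by boundary contact: any voxel in the first
or last section, on the image border, or 8-adjacent in-plane to an
out-of-core pixel disqualifies the component (its detachment cannot be
demonstrated inside the analyzed cylinder); the bulk tumor is by
construction in this excluded set, and the largest boundary-touching
component is reported as the bulk. Every interior component is a
discohesive focus — interior components are necessarily enclosed by stroma
within the analyzed volume.

`validate_detachment()` is the dilation half of a dilation/shrinkage
continuity check: each focus is dilated by one voxel (26-neighbourhood)
and flagged if the envelope touches any other parenchyma component. With
26-connected labeling this flag is necessarily TRUE for every correctly
partitioned focus (a voxel within Chebyshev distance 1 of a focus would
already belong to it), so it serves as an always-on consistency assertion,
never a reclassification.

Per focus, `focus_stats()` reports volume, equivalent sphere diameter, and
Ki67$^+$/Ki67$^-$ nucleus counts by centroid membership (simple,
deterministic; overlap-fraction assignment was rejected as needlessly
complex for objects wholly inside a focus). `size_histogram()` rounds each
diameter to the nearest integer micrometer and bins into the classes
`<16`, `16–20`, `21–25`, …, `46–50`, `51–200`, `>200`; rounding first is
what makes the printed integer class labels (with their apparent 1-µm
gaps) a contiguous cover.

### Border area and case statistics

`border_area()` delineates the parenchymal–stromal border as a plane one
voxel wide and sums voxel-face areas with the correct anisotropy (x-normal
faces $d_y d_z$, y-normal $d_x d_z$, z-normal $d_x d_y$). Faces against
out-of-core or out-of-stack space are not part of the border. Face
counting overestimates a smooth surface by a known factor — for a digital
ball of radius 20 voxels the tests pin the ratio to 4πr² inside
[1.4, 1.6], the theoretical value being 1.5 — which cancels in $S/V_p$
comparisons between cases processed identically; a smoothed mesh estimator
was deliberately not used, to stay faithful to the voxel-border
definition.

`case_morphometry()` assembles the per-case record ($V_p = 0$ yields NA
ratios, never zeros), `group_summary()` reports means with sample
(n−1) standard deviations — the convention verified against the reference
series' printed 18.2 / 45.5 / 40.6 — and `depth_class()` applies the
strict boundaries shallow < 3 mm ≤ intermediate ≤ 5 mm < deep. The
invasion mode (PB / TSC / DS / SF) is pass-through metadata: automatic
architecture classification is out of scope.

## The phantom generator

`phantom_spec()` + `build_phantom()` + `render_stack()` emulate the study
conditions end-to-end. Geometry archetypes: **PB** — one dome anchored
through the first section with short finger-like projections; **TSC** — a
connected honeycomb of jittered cords (a spanning-tree construction
guarantees one component); **DS** — a compact mass plus many small
detached foci; **SF** — a few thin tortuous strands random-walking down
the stack. Planted foci are spheres meeting a 2-voxel separation
constraint (guaranteeing 26-disconnection), kept strictly between the
first and last sections and 16 px clear of the lateral core margin —
marginal foci would be boundary-excluded anyway, and the margin keeps the
nominal analysis cylinder valid after registration re-frames the stack by
the (unknowable) true transform of the reference slice.

Default conditions, chosen once for realism:

* grid 512 × 512 × 40 voxels at 0.92 µm/px and 4 µm sections (a
  desk-scale reduction; the full 3-mm/100-section geometry is supported
  and its cylinder volume, π·1.5²·0.4 ≈ 2.83 mm³, matches the reference
  series' printed totals); core diameter 90% of the grid;
* focus plan 18 µm ×4, 22 µm ×3, 28 µm ×2, 40 µm ×1 — ten foci with the
  size distribution's bulk in the 16–25 µm classes, as in the reference
  series;
* nuclei of radius 3.5 µm (7-µm nuclei always span at least two 4-µm
  slabs, so the two-slice filter never deletes a true nucleus);
  parenchymal density 2×10⁵/mm³ with Ki67 fraction 0.5 — a Ki67$^+$
  density of 10×10⁴/mm³, mid-range of the reference series' printed
  5.0–32.0 — and stromal Ki67$^+$ density 2×10⁵/mm³ (inflammatory and
  endothelial proliferation);
* per-slice misalignment uniform within ±8 px and ±2°, Gaussian intensity
  noise SD 0.02 on the [0, 1] scale.

Nucleus placement uses Poisson counts with a class-aware hard core
(a Matérn-II-type rejection): within a marker class, two nuclei must be
separated either in-plane by more than the sum of their footprint radii
plus two pixels or axially by enough slabs that their section footprints
can never become 26-adjacent; across classes a spherical hard core
applies. Real epithelium is denser and nuclei clump — the published method
counts connected objects and explicitly does not split touching nuclei —
but the phantom's purpose is parameter recovery, so it is built so that
object counting and nucleus counting coincide exactly. Ki67$^-$ nuclei
(and all parenchymal nuclei) are sampled from the eroded interior of the
parenchyma so each is wholly inside its compartment and every hole is
fully circumscribed; one consequence is that thin structures (TSC cords,
SF strands) carry no parenchymal nuclei, which the truth table reflects.
Stromal nuclei are generated Ki67$^+$ only: the model has no counterstain,
so a Ki67$^-$ stromal nucleus would be unobservable.

Rendering works per 4-µm slab, not per plane: a nucleus footprint on a
section is the projected disk of its sphere–slab intersection. Ki67$^-$
nuclei are carved out of the DAB concentration map (unstained holes in
cytoplasm); the carved mask is stored as the ground-truth `cytoplasm`
volume, and recovery comparisons (Dice, $V_p$) run against it — it is what
CK staining can physically show, and the digital $V_p$ of the published
workflow likewise excludes the "open" Ki67$^-$ spaces. Stroma renders at
blank-slide intensity (no counterstain is modelled). RNG streams are split
per concern (geometry / foci / nuclei / misalignment / noise), so changing
the noise level never changes the geometry, and a fixed seed reproduces
the phantom bit for bit.

What the phantom does **not** emulate: histological texture of stroma and
muscle, tissue folds and tears, deformable section distortion, stain
intensity gradients, and densely clumped nuclei. Passing recovery tests
therefore demonstrate the correctness of the algorithms under the stated
geometry and staining model, not segmentation performance on real slides —
in particular, real-data registration relies on far richer texture, and
real nucleus counts are connected-object counts.

## Numerical choices and degenerate inputs

* Otsu thresholds are computed on a 256-bin histogram; the brute-force
  between-class-variance oracle in the tests agrees on the induced split.
* `rgb_to_od()` floors intensities at 1/255 (one 8-bit quantum) before the
  log; OD is clamped at zero so blank-slide pixels carry no stain.
* Constant images are rejected by registration ("no registrable content"),
  and `register_stack()` names the offending slice pair on failure.
* An unsatisfiable focus plan fails with the first unplaceable focus named
  after 1000 rejection-sampling attempts.
* Empty parenchyma yields an empty partition, zero volumes, and NA ratio
  statistics (never silent zeros).
* Transform composition/inversion is exact to 1e-9 px/deg; masks pass
  through nearest-neighbour resampling and stay binary.
* Coordinates are 1-based pixel/voxel centers; z increases with section
  number; voxel `k` spans the slab `[k-0.5, k+0.5]` in slice units.

## Problem sizes used by the tests and the acceptance script

Recovery tests run at desk scale: a 112 × 112 × 18 voxel PB phantom with
three planted 18-µm foci for the shared fixtures, 112 × 112 × 24 for the
four-archetype segmentation checks, 160 × 160 × 32 (ten planted foci) for
the archetype recovery matrix, and 160 × 160 × 40 for the 40-slice
registration recovery. The acceptance script re-runs the same measurements
from scratch at these sizes, plus the reference-series recomputations and
the full-scale core-geometry check. These sizes were chosen so the whole
validation battery runs comfortably on a laptop while keeping every
planted structure several voxels wide.

## Known limitations

* The detachment flag cannot be FALSE under the 26/26 scheme (see above);
  it is a consistency assertion.
* $S$ is a face-count area: absolute values carry the ≈1.5× digital bias;
  only ratios between identically processed cases are comparable to
  smooth-surface areas.
* One case of the bundled reference series (case C) is internally
  inconsistent at printed precision — its printed parenchyma volume cannot
  be reconciled with its printed percent, $S/V_p$ and Ki67 density, which
  all imply a $V_p$ near 0.63 mm³ rather than 0.56.
  `check_reference_consistency()` flags exactly that case and the test
  suite asserts the flag, without attempting a reconciliation.
* Whether a "whole tissue volume" should be the full core cylinder or a
  segmented tissue footprint is a modelling choice; the package uses the
  full cylinder (consistent with the reference totals) and exposes the
  core diameter as a parameter.
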