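# tumor3d

Histology-based 3D reconstruction and invasion-front morphometry of oral
tongue squamous cell carcinoma (OTSCC) serial sections.

Invasion is a three-dimensional process, but tumors are graded from
two-dimensional slides: an "isolated" cancer island on a section may be a
cut through a cord that is connected to the main mass out of plane.
`tumor3d` reconstructs the deep invasion front from a stack of 80–120
double-immunostained serial sections of a 3-mm tissue core
(pan-cytokeratin/DAB marking carcinoma cytoplasm, Ki67/Vector SG marking
proliferating nuclei; 0.92 µm/pixel, 4 µm sections) and quantifies the
architecture:

* **rigid registration** of consecutive sections ("rough and fine":
  Fourier/NCC search plus a nucleus-centroid Procrustes refinement;
  strictly translation + rotation — no stretching);
* **colour deconvolution** (Beer–Lambert optical density, Ruifrok–Johnston
  unmixing) into DAB and SG concentration maps, pooled-Otsu segmentation
  of CK⁺ parenchyma and Ki67⁺ nuclei, Ki67⁻ nuclei as open spaces
  circumscribed by CK⁺ cytoplasm, stroma by subtraction;
* **anisotropic voxel assembly** (no z interpolation; z depth = section
  thickness) restricted to the core cylinder, with the two-consecutive-
  section nucleus noise filter;
* **discohesive cancer foci**: 26-connected parenchyma components fully
  detached from the main mass and completely surrounded by stroma, with
  boundary exclusion, a dilation-based detachment QC flag, equivalent
  sphere diameters `d = (6V/π)^(1/3)` and per-focus Ki67⁺/Ki67⁻ counts;
* **case morphometry**: tissue/parenchyma/stroma volumes, the
  parenchymal–stromal border area `S` by one-voxel-plane face counting,
  the shape-complexity index `S/Vp` (mm⁻¹), Ki67 density (×10⁴/mm³),
  focus counts, size-class histograms, and CSV report writers.

Because the original image stacks are not public, the package includes a
first-class synthetic phantom generator for the four canonical invasion
architectures (pushing-bulky, trabecular, diffuse-spreading, special
forms), rendered into misaligned, noisy, double-chromogen RGB sections
with full voxel ground truth — every pipeline stage is validated by
parameter recovery. A reference 14-case morphometry series is bundled
(`reference_cases()`, `reference_focus_sizes()`) for consistency checks of
all derived statistics.

## Worked example

Generate a diffuse-spreading phantom with ten planted discohesive foci,
render it into misaligned noisy sections, and run the full pipeline:

```r
library(tumor3d)

spec <- phantom_spec("DS", grid = c(160, 160, 32),
                     focus_plan = list(c(20, 6), c(26, 4)), seed = 11)
gt <- build_phantom(spec)
gt
#> ground_truth (DS): 160 x 160 x 32 voxels, 10 planted foci, 350 nuclei

stack <- render_stack(gt)           # default: ±8 px / ±2° mounting error,
stack                               # 2% intensity noise
#> section_stack: 32 slices of 160 x 160 px, 0.92 um/px, 4 um thick

res <- analyze_stack(stack, core_diameter_um = gt$core_diameter_um,
                     case_id = "phantom-DS", invasion_mode = "DS")
res
#> tumor3d case 'phantom-DS' (DS):
#>   tissue 0.00177 mm3, parenchyma 0.000169 mm3 (9.6%)
#>   border S = 0.0468 mm2, S/Vp = 277.2 1/mm
#>   Ki67+ in parenchyma: 19 (11.2 x10^4/mm3)
#>   discohesive foci: 10 (31.8% of Vp)
```

All ten planted foci are recovered through registration, segmentation and
3D partitioning; their equivalent diameters land in the expected size
classes:

```r
res$size_histogram
#>    <16  16-20  21-25  26-30  31-35  36-40  41-45  46-50 51-200   >200
#>      0      6      4      0      0      0      0      0      0      0

head(res$foci[, c("id", "volume_um3", "equivalent_diameter_um",
                  "detachment_confirmed")], 3)
#>   id volume_um3 equivalent_diameter_um detachment_confirmed
#> 1  2   3256.947               18.39094                 TRUE
#> 2  3   3714.003               19.21386                 TRUE
#> 3  4   3697.075               19.18462                 TRUE
```

The planted foci were 20 and 26 µm spheres; the recovered diameters
(18.4–19.4 µm for the first group) carry the expected digitization and
segmentation bias of a ~1 µm/px reconstruction. The `S/Vp` of 277 mm⁻¹
reflects the tiny desk-scale core (132 µm): surface-to-volume indices
shrink as structures grow, which is why cases are only compared at equal
scale.

Group statistics of the bundled reference series reproduce the published
means and sample SDs:

```r
group_summary(reference_cases())
#>   group n     mean        sd
#> 1    DS 3 136.4667  40.57491
#> 2    PB 5  78.6000  18.17856
#> 3    SF 2 486.3000 514.34947
#> 4   TSC 4  81.6250  45.46767
```

(78.6 ± 18.2 mm⁻¹ for pushing-bulky, 81.6 ± 45.5 for trabecular,
136.5 ± 40.6 for diffuse spreading.)

`write_reports()` emits the per-case CSV tables (metadata, morphometry at
printed precision, per-focus tables, size-class histogram) plus a run
manifest; `write_stack()`/`read_stack()` persist section stacks as
numbered 8-bit RGB TIFFs with a plain-text sidecar.

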