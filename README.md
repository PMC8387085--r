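# canmorph

Quantitative histomorphometry of **bile canaliculi** in brightfield
photomicrographs of CD10 immunohistochemistry-stained liver sections.

Canalicular pathology is hard to quantify in routine biopsies: the
canaliculi are thin, branched, and only visible as the brown DAB product of
the CD10 stain over a hematoxylin counterstain. canmorph implements the
full measurement chain for two-group studies on such material — and, since
clinical images can rarely be shared, a seeded synthetic-field generator
with ground truth so that every stage of the chain is verifiable.

The pipeline per field:

1. **Stain separation** — Beer–Lambert color deconvolution in the
   Ruifrok–Johnston H-DAB basis; a pixel is IHC-positive when its total
   stain optical density exceeds a floor (0.05) and the DAB share of it is
   ≥ 0.5. Non-positive pixels are forced to white, positive pixels are
   re-rendered from their DAB component alone.
2. **8-bit + threshold** — rounded unweighted channel mean; positive = dark.
   Default threshold 250 keeps all extracted pixels; Otsu on the sub-255
   histogram is available as `"auto"`.
3. **ROI morphometry** — 8-connected components, components < 10 px removed
   as artefacts; per ROI: area (µm²), corner-corrected perimeter *P* (µm),
   axis-projection Feret diameter *F* = (X + Y)/2 (µm), **P/F** (the
   branching index: branches lengthen the boundary much faster than the
   span, so branched profiles score higher; a disk sits at π), solidity
   (area / convex-hull area), MGV and cMGV = 255 − MGV (absorbance-like
   staining intensity).
4. **Thickness** — whole-field mean canalicular thickness in µm by the 2-D
   largest-inscribed-disk (trabecular-style) local thickness transform,
   exact against a brute-force oracle.
5. **Statistics** — fields average to patients (default unit), two-sided
   pooled-variance Student's t-test per parameter (Welch optional),
   mean ± SD descriptives, subgroup tables without tests.

## Worked example

```r
library(canmorph)

spec <- synthetic_spec(seed = 42)          # one 64 µm synthetic field
g <- generate_field(spec)
g$field
#> <calibrated_field> synthetic / field 1 (control)
#>   256 x 256 px, 0.25 um/px (64 x 64 um)

sm <- threshold_mask(to_8bit(extract_dab(g$field)), threshold = 250)
sm
#> <stain_mask> 256 x 256 px, 3210 positive (4.90%), threshold 250 [hdab-deconvolution/manual]

rois <- measure_rois(sm, scale = spec$scale)
round(head(rois[, c("roi_id", "pixel_count", "area", "perimeter",
                    "feret", "pf_ratio", "solidity", "cmgv")], 3), 3)
#>   roi_id pixel_count   area perimeter  feret pf_ratio solidity    cmgv
#> 1      1         763 47.688    57.431 12.125    4.737    0.543 153.043
#> 2      2        1344 84.000   117.129 19.375    6.045    0.378 153.208
#> 3      3         674 42.125    63.234  9.875    6.403    0.514 153.203

local_thickness(sm, spec$scale)
#> <thickness_map> 256 x 256 px, mean thickness 1.603 um
```

Each row is one canalicular profile: the second ROI covers 84 µm², its
boundary (117 µm) is six times its span (19.4 µm) — a strongly branched
profile (pf_ratio 6.0, solidity well below 1) — and it stains at
cMGV ≈ 153 of 255. The field's canaliculi average 1.6 µm in thickness.

A whole study, with a hypo-branching effect injected into the disease
group:

```r
dir <- tempfile()
manifest <- run_simulate(dir, n_disease = 3, n_control = 3,
                         fields_per_sample = 3,
                         disease_spec = list(branch_count = 0), seed = 42)
run_measure(manifest, file.path(dir, "out"), run_config())
res <- run_compare(file.path(dir, "out", "fields.csv"),
                   file.path(dir, "cmp"), run_config())
res$comparison
#> Two-group comparison (patient level): disease (n=3) vs control (n=3)
#>   area             27.188 ± 1.139    vs   39.902 ± 3.795     t= -5.56  p=0.00513
#>   perimeter        46.662 ± 1.707    vs   62.253 ± 7.925     t= -3.33  p=0.0291
#>   ...
#>   pf_ratio          4.298 ± 0.051    vs    5.044 ± 0.264     t= -4.81  p=0.00859
#>   solidity          0.452 ± 0.021    vs    0.465 ± 0.022     t= -0.72  p=0.51
#>   mean_thickness    1.183 ± 0.014    vs    1.370 ± 0.074     t= -4.33  p=0.0123
```

The removed branches depress perimeter-driven parameters (area, perimeter,
P/F) while solidity — which the effect does not target — stays
indistinguishable. `run_measure` writes `rois.csv`/`fields.csv` and
`run_compare` writes a wide report table plus JSON, all with provenance
headers echoing the configuration.

A thin command-line front end over the same functions ships at
`inst/scripts/canmorph` (`simulate`, `measure`, `compare` subcommands; flat
YAML config plus flag overrides).

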