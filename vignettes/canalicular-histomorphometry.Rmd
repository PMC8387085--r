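---
title: "Canalicular histomorphometry: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canalicular histomorphometry: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canmorph)
```

## The measurement problem

Bile canaliculi — the channels formed between the apical membranes of
adjacent hepatocytes — are highlighted in routine liver biopsies by CD10
immunohistochemistry: the DAB reaction product stains the canalicular
membrane brown against a blue hematoxylin counterstain. canmorph quantifies
canalicular morphology from RGB photomicrographs of such sections: each
high-power field is segmented into IHC-positive regions of interest (one
connected DAB profile = one canalicular profile), each profile is measured,
fields aggregate to patients, and patients are compared between two groups.

The one non-standard statistic in the chain is the **perimeter-to-Feret
ratio** (P/F), a branching index: side branches lengthen a profile's
boundary much faster than they extend its overall span, so a more branched
canaliculus has a larger P relative to F. For a smooth unbranched profile
P/F sits near $\pi$ (a disk has $P/F = \pi d / d = \pi$ under the Feret
definition used here); branching pushes it up.

## Stain separation

Pixels are unmixed by Beer–Lambert color deconvolution. Each RGB intensity
$I_c$ becomes an optical density $A_c = -\log_{10}(I_c/255)$, and the OD
vector is expressed in the H-DAB basis (the published Ruifrok–Johnston
hematoxylin and DAB vectors, completed by their unit cross product):
$A = \sum_k c_k \, v_k$, with $c_k$ the per-stain densities. A pixel is
called DAB-positive when

* its total (non-negative) stain density exceeds a background floor
  (`od_floor`, default 0.05 OD — below this a pixel is effectively white),
  and
* the DAB share of that total is at least `dab_fraction` (default 0.5 — the
  pixel is *predominantly* brown).

`extract_dab()` re-renders positive pixels from their DAB component alone
and forces everything else to pure white, so the downstream 8-bit channel
has background exactly at 255. The 8-bit conversion is the rounded
*unweighted* channel mean, matching the default conversion of the common
desktop image-analysis workflow (ITU-R luma weights are available). The
positive = dark convention matters: the corrected mean gray value
cMGV = 255 − MGV is an absorbance-like quantity and is only meaningful when
stained pixels have *low* gray values.

Thresholding is an explicit, recorded parameter. The default of 250 keeps
every extracted pixel ("select all IHC-positive areas, with no overlap with
the background"); `threshold = "auto"` is Otsu's criterion computed on the
sub-255 histogram only. Note what "auto" is for: it splits a *bimodal
foreground* (e.g. strong canalicular staining over weak diffuse blush); on
a unimodal foreground it will cut through the single mode and discard
roughly half of it, which is why it is not the default.

## ROI morphometry

Connected components are taken under 8-connectivity (one-pixel-wide
canaliculi remain connected across diagonals) and ordered deterministically
by their top-left-most pixel. Components under 10 pixels are removed as
artefacts; the rule is exclusive, so a 9-pixel component is dropped and a
10-pixel component kept.

Per ROI, with $s$ the calibration in µm/px:

* **area** = pixel count × $s^2$;
* **perimeter**: the crack (pixel-edge) boundary measured with every
  90° corner cut — straight unit steps weigh 1 and each cut corner replaces
  two half-edges by a $\sqrt2/2$ diagonal, i.e. $P = E - C(1 - \sqrt2/2)$
  from the crack-edge count $E$ and corner count $C$. This estimator is
  exact (up to the four outer corners) on axis-aligned rectangles and puts
  a digitized disk's P/F within 5% of $\pi$; a pixel-center chain walk was
  rejected because it is biased low by $4/n$ on an $n$-px square and fails
  the square anchor;
* **Feret diameter**: the arithmetic mean of the widths of the projections
  onto the image x and y axes, $F = (X+Y)/2$. This is deliberately *not*
  the conventional maximum caliper: the axis-projection mean is the
  construction the branching index is defined against. It is
  orientation-dependent (rotating a square by 45° changes it by $\sqrt2$);
  `feret_mode = "caliper"` provides the rotational maximum for comparison;
* **pf_ratio** = P/F, dimensionless and scale-free;
* **solidity** = pixel area / convex-hull area, with the hull taken over
  the *outer corners* of the pixels so any convex digitized region (e.g. a
  filled rectangle) scores exactly 1;
* **MGV / cMGV**: mean gray value over the ROI on the *extracted* 8-bit
  channel (not a grayscale of the original RGB — the extraction already
  removed background and counterstain, which is what makes cMGV
  interpretable without further normalization), and cMGV = 255 − MGV.

Border-touching ROIs are kept by default (`exclude_border` enables the
sensitivity variant).

## Local thickness

Whole-field canalicular thickness uses the largest-inscribed-disk
definition: the thickness at a foreground pixel is the diameter of the
largest disk containing that pixel and lying entirely within the
foreground; the per-field value is the mean over foreground pixels. This is
the standard trabecular-thickness measure of bone microarchitecture,
adopted here because a canalicular network tiles a field much as trabeculae
do. It is computed from the exact Euclidean distance transform (outside the
image counts as background), with inscribed radius $r(c) =
\mathrm{EDT}(c) - 1/2$ and pixel-center disk membership — calibrated so a
solid bar spanning $w$ pixel rows measures exactly $w$. Redundant centers
are pruned by neighbour domination ($r(n) \ge r(c) + \lVert c-n \rVert$
implies disk inclusion) and the surviving ridge disks are painted in
decreasing radius order; the result is pixel-for-pixel identical to the
exhaustive brute-force search, which the test suite verifies on random
masks. Thickness is computed on the unfiltered mask ("whole images"); a
flag applies the artefact filter first. Known property: on digitized bands
the measure carries a lattice anisotropy of up to one pixel (diagonal
orientations measure thin), so thin-structure thickness is accurate to
about ±1 px, not better.

## Statistics

The default analysis unit is the **patient**: each patient's value is the
mean over their non-empty fields (the sampling design is 6 random
high-power fields per slide). Group comparison is a two-sided
pooled-variance Student's t-test (Welch optional), descriptives are sample
mean ± SD, and no multiple-testing correction is applied by default (a Holm
option exists). Subgroup splits (clinical liver disease vs none) are
descriptive only — no tests — because the subgroups are tiny. Field- and
ROI-level units are available, but note the caveat: fields within a patient
are correlated, so sub-patient units overstate the effective sample size (a
mixed model would be the statistically superior design and is deliberately
out of scope).

## The synthetic generator

`generate_field()` renders fields for which every downstream answer is
known. Each canaliculus is a random-walk main axis (`segment_length`,
per-step turning SD `tortuosity`) with `branch_count` side branches
sprouting at uniformly random positions, deflected 30–90° off the local
heading, one third of the main axis in length. The axis is dilated to a
tube: a pixel is painted when its center lies within `tube_width/2` of the
densely sampled polyline, which gives the band the same width in every
direction (integer-disk painting was rejected: it is ~1 px thin on
diagonal runs). Stained pixels carry `dab_od` along the DAB basis vector;
the background carries a smooth random hematoxylin texture around
`background_od`; transmittances follow Beer–Lambert through exactly the
basis the extraction inverts, then Gaussian noise (`noise_sd` gray levels)
is added and the image quantized to 8 bits. A fixed seed fixes the output
bit-exactly.

Defaults, chosen once for realism at high power: 256 × 256 px at
0.25 µm/px (a 64 µm field), 8 canaliculi per field, tubes 5 ± 1 px
(≈ 1.25 µm, the calibre of a normal canaliculus), 2 branches each,
DAB OD 0.8, hematoxylin OD 0.15, noise σ = 3.

What the generator does *not* emulate: hepatocyte texture and organelles,
Gaucher-cell infiltrates, steatosis vacuoles, chromatic aberration,
uneven illumination, or stain-vector drift between slides. Passing the
recovery suite therefore shows the measurement chain is faithful to its own
model of a field — it does not certify performance on clinical material,
where stain variation and confluent background are the dominant
difficulties.

Test problem sizes were chosen to keep the suite quick while leaving the
conclusions stable: 100 random 64 × 64 masks for the thickness oracle, 50
seeded replicates per arm for the branching contrast on 192 × 192 fields,
2000 null replicates for t-test calibration.

## Numerical and degenerate-input choices

* OD computation floors intensities at 1/255 so black pixels stay finite.
* Otsu on an all-equal sub-255 foreground (zero variance everywhere)
  returns that single level, so the mask covers the whole foreground; an
  all-white image is an error ("no foreground signal").
* Empty masks: thickness is reported missing with a warning; empty fields
  are flagged (`n_roi = 0`) and excluded from aggregation with a warning.
* Zero within-group variance with separated means: t is reported as
  ±Inf with the smallest positive p and a degeneracy warning, keeping
  p in (0, 1].
* Component labeling, ROI ordering, and CSV serialization are fully
  deterministic: the same inputs and configuration yield byte-identical
  outputs.

## Known limitations

* The axis-projection Feret is orientation-dependent by construction; this
  is a property of the definition, documented rather than "fixed".
* The perimeter estimator is ~5% high on smooth curved contours (staircase
  bias); the disk anchor P/F ≈ 1.048 π quantifies it. Branching contrasts
  are unaffected since both arms share the bias.
* An axis-aligned plus-shaped region has the *same* continuum perimeter as
  its bounding square (any rectilinear staircase-monotone outline measures
  the box perimeter), so axis-aligned crosses do not raise P/F; the
  branching index responds to *angled* branches, which is what canalicular
  networks contain.
* Local thickness inherits EDT lattice anisotropy (±1 px on thin diagonal
  structures).
* cMGV is a relative absorbance proxy; without cross-slide stain
  normalization (out of scope) it is comparable only within a staining
  batch.
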