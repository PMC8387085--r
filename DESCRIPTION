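Package: canmorph
Title: Canalicular Histomorphometry from CD10-Stained Liver Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative histomorphometry of bile canaliculi in brightfield
    photomicrographs of CD10 immunohistochemistry-stained liver sections.
    Separates the DAB (brown) reaction product from the hematoxylin
    counterstain by color deconvolution, thresholds the 8-bit stain channel
    into canalicular regions of interest, and measures per-canaliculus area,
    perimeter, axis-projection Feret diameter, solidity, mean gray value and
    its absorbance-like complement, together with the perimeter-to-Feret
    ratio used as a branching index. Whole-field canalicular thickness is
    estimated with a two-dimensional local-thickness (largest inscribed
    disk) transform. Field measurements aggregate to patients and two-group
    comparisons with Student's t-test; a seeded generator of synthetic
    DAB-stained branching networks with ground truth makes the whole chain
    verifiable without clinical material.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    withr,
    yaml,
    grDevices,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
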