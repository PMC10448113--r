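Package: glomap
Title: Quantification of Functional Odor Maps in the Larval Amphibian Olfactory Bulb
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for odor maps recorded by volumetric
    calcium imaging in the larval Xenopus laevis olfactory bulb. Turns
    ROI-level fluorescence time series into baseline-corrected dF/F traces,
    response peak amplitudes and signal-to-background ratios; classifies
    default and dominant odor tuning against an eight amino-acid panel;
    computes lifetime sparseness, correlation matrices, average-linkage
    stimulus clustering and normalized cluster distances; tests glomerular
    chemotopy via species territories, inter-centroid distances and
    compound-profile centroid deviations; scores molecular similarity of the
    stimulus panel from first principles (exhaustive connected maximum common
    substructure and Carhart atom-pair Tanimoto coefficients); analyzes
    mitral/tufted-cell morphology (density-based tuft detection, convex-hull
    tuft volumes, nine-feature PCA) and multicolor dendritic projections
    (2:1 color-ratio voxel classification). A synthetic-data module generates
    every input with exported ground truth so the full pipeline is testable
    without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
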