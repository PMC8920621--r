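Package: dermamesh
Title: Marching-Cubes Surface Reconstruction of Skin Slice Stacks and
    Psoriasis Severity Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assembles stacked grayscale slice images (DICOM series, raster
    stacks, or raw binary grids) into scalar volumes and extracts
    triangulated isosurfaces with the classic marching-cubes case tables,
    offering both linear edge interpolation and a division-free midpoint
    ("median") vertex placement, with central-difference gradient normals.
    Includes mesh deduplication, topology reports and STL/OBJ/PLY export,
    synthetic analytic test volumes, a benchmark comparing the two
    interpolation modes, and the clinical evaluation calculus for psoriasis
    treatment studies: PASI scoring over four body regions, before/after
    PASI reduction, the four-level itching scale, efficacy categorisation
    with total effective rates, and Welch t and chi-square group
    comparisons from summary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
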