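Package: rtcurate
Title: Bulk Curation of DICOM-RT Datasets into Analysis-Ready Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated curation of raw DICOM and DICOM-RT datasets (CT image
    series, RT structure sets, RT plans, RT dose grids) into analysis-ready
    NIfTI and NRRD volumes. A crawler indexes the metadata of every DICOM file
    under a directory into a shareable series-level index; a connector links
    series of different modalities into coherent per-patient samples through
    DICOM reference metadata, with frame-of-reference and study fallback
    heuristics for files with missing references; a processor resamples
    images, clips intensities to a Hounsfield window, rasterizes contours
    into segmentation masks and aligns dose grids onto the image geometry.
    A single pipeline command runs all three stages in bulk, deterministically
    and in parallel, and can emit nnU-Net style dataset layouts. Includes a
    deterministic synthetic DICOM fixture generator with analytic ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    parallel,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
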