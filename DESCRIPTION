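Package: obsm
Title: Occlusion-Based Saliency Maps and Multi-Reader Annotation Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for explaining volumetric image classifiers with
    occlusion-based saliency maps (systematic patch masking against a
    pluggable malignancy scorer, upsampling to native resolution, peak-slice
    selection and colour overlays) and for analysing multi-reader rectangle
    annotations of the highlighted regions: free-text normalisation against a
    radiology lexicon, topic extraction, geometric-median spatial clustering
    of annotation anchors, per-region agreement summaries and Mann-Whitney
    group comparisons. Includes a synthetic phantom and reader-study
    generator so the full pipeline is testable without access to clinical
    scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
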