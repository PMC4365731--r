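Package: rsagram
Title: Representational Similarity Analysis of Grammatical Processing Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for region-of-interest representational
    similarity analysis (RSA) of multivoxel fMRI patterns elicited by a
    12-condition grammatical design (bare stems, inflected forms and minimal
    phrases, crossed with four verb/noun dominance categories). Computes
    correlation-distance representational dissimilarity matrices (RDMs) from
    voxel-by-condition pattern matrices, averages them across participants,
    fits categorical and dominance-weighted hypothesis model RDMs by
    second-order rank correlation with condition-label permutation inference,
    applies Storey q-value or Benjamini-Hochberg false discovery rate control
    across regions, compares competing models with subject-level sign-flip
    tests, and embeds region-model relations with classical multidimensional
    scaling. Includes volumetric ROI utilities (NIfTI masks, sphere ROIs,
    anterior/posterior splits, pattern extraction) and a synthetic
    multi-subject study generator with planted representational geometry, so
    every stage of the pipeline is verifiable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
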