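Package: lesionparc
Title: Data-Driven Vascular Parcellation and Lesion-Symptom Mapping of Stroke Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for data-driven parcellation of stroke lesion data and
    lesion-symptom mapping. Decomposes patient cohorts of voxel-wise lesion
    abnormality maps into varimax-rotated principal components whose spatial
    layout reflects the vascular-territory covariance of middle-cerebral-artery
    stroke, with eigenspectrum information criteria (MDL, KIC) for model-order
    selection. Reduces multi-test neuropsychological batteries to orthogonal
    behavioural factors, and relates lesions to behaviour by voxel-based
    correlational mapping with permutation cluster correction, component-factor
    correlation, and stepwise regression with brain back-projection. Includes a
    simulation framework that generates synthetic vascular atlases, lesion
    cohorts and behavioural batteries with known ground truth, and quantifies
    the spatial displacement error and Dice overlap of competing lesion models
    (single voxel, anatomical atlas, vascular-territory components) and
    inference methods (mass-univariate Fisher/FDR, sparse canonical
    correlation, component regression).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
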