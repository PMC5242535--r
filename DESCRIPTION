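Package: hdpheno
Title: Longitudinal MRI and Histopathology Phenotyping for Mouse Models of
    Huntington's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable re-implementation of a longitudinal imaging and
    histopathology phenotyping pipeline for knock-in mouse models of
    Huntington's disease, run end-to-end on synthetic data with known ground
    truth. Provides a seeded synthetic-data layer (labelled ellipsoidal brain
    phantoms with genotype-dependent growth-then-atrophy trajectories,
    multi-echo spin-echo renderings, behavioural cohort tables, histology
    section images); multi-echo T2 relaxometry (echo summation, mono-exponential
    fitting, ROI means with a muscle internal control); ROI volumetry with
    percent-change and genotype-gap summaries; linear (6/9 dof) and viscous-fluid
    non-rigid registration with Jacobian-determinant maps; voxel-wise
    tensor-based morphometry statistics (Welch t maps, permutation testing with
    a pooled voxel null and Benjamini-Hochberg FDR); design-based stereology
    (Cavalieri volumes, optical fractionator counts, Gundersen-Jensen
    coefficient of error); threshold-based immunoreactivity quantification and
    cortical thickness measurement; and the cohort statistics layer (Grubbs
    outlier screening, factorial Type III ANOVA, Bonferroni-corrected Pearson
    correlation matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    RNifti,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
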