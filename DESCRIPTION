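Package: tsmorph
Title: Triceps Surae Muscle Morphometry and Shape-Factor Volume Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs skeletal-muscle morphology from slice-wise MRI
    segmentation contours and implements the shape-factor model of muscle
    volume for the triceps surae (soleus, gastrocnemius medialis and
    lateralis). Computes anatomical cross-sectional area (ACSA) profiles,
    muscle length, measured volume by trapezoidal integration, the maximal
    ACSA and its position along the shank, and the dimensionless shape
    factor p = V / (ACSA_max x L). Provides simplified volume estimation
    from ACSA_max and muscle length via cohort shape-factor tables,
    method-agreement statistics (relative RMS difference, R-squared,
    coefficient of variation, paired t test with normality check, one-way
    ANOVA with Bonferroni post hoc), and a synthetic-cohort generator of
    unimodal muscle phantoms with known morphology for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    nortest,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    RNifti,
    optparse
Config/testthat/edition: 3
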