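Package: fcanomaly
Title: Patient-Specific Functional Connectome Anomaly Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies patient-specific anomalies of the voxel-wise functional
    connectome against a normative control cohort. Voxel-wise connectivity is
    measured with Fisher z-transformed Pearson correlation, each voxel's
    connectivity profile is compared to a control-average reference by
    positive-clipped cosine similarity, and deviations are expressed as robust
    (median/MAD) anomaly scores with lesion-voxel exclusion. Downstream analyses
    attribute anomaly to functional proximity versus spatial distance from a
    lesion, quantify bi-hemispheric and cerebellar network symmetry via
    lesion-network maps, characterise longitudinal post-surgical trajectories
    with quadratic trends, and test whether local anomaly precedes the location
    of segmented tumour recurrence (permutation tests and Mann-Whitney AUC).
    A synthetic-cohort module generates phantom brains with mirrored
    seven-network structure and crossed cerebellar representation so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
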