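Package: fcdmap
Title: Distance-Dependent Functional Connectivity Density Mapping for
    Resting-State fMRI
Version: 0.1.0
Authors@R: person("fcdmap", "developers", role = c("aut", "cre"),
    email = "fcdmap@example.org")
Description: Computes voxelwise global, short-range, and long-range
    functional connectivity density (FCD) maps from resting-state fMRI
    time series, partitioning connections by Euclidean distance at a
    configurable criterion (12 mm by default). Includes a minimal NIfTI-1
    reader/writer, a BOLD preprocessing chain (initial volume dropping,
    head-motion screening, Friston-24 nuisance regression, spatial
    smoothing, temporal band-pass filtering), voxelwise ANCOVA with
    Gaussian-random-field cluster-level correction, post-hoc effect
    sizes, clinical-score regression with Benjamini-Hochberg FDR,
    leave-one-out reproducibility mapping, seed-based functional
    connectivity, lesion overlap tools, summary-statistic group tests,
    ANOVA power, and a synthetic three-group cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
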