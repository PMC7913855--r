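Package: handsyn
Title: Synergy-Based Sensor Reduction for Whole-Hand Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the minimal set of hand joint angles that must be
    recorded to reconstruct whole-hand kinematics. From multi-subject,
    multi-task recordings of the 16 canonical hand degrees of freedom, the
    package extracts per-subject kinematic synergies (PCA with Varimax
    rotation on standardized angles), clusters the pooled loading vectors
    across subjects with complete linkage on the angle-between-components
    distance, classifies the clusters into independent angles and
    coordination groups, enumerates candidate representative sets, fits
    linear (affine) estimators for the non-recorded angles by ordinary
    least squares, and evaluates estimation error on held-out recordings
    in degrees and as a percentage of each joint's range of motion. A
    synthetic cohort generator with planted synergy structure makes every
    pipeline stage testable without access to motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
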