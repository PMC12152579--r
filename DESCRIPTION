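Package: alpstraj
Title: Glymphatic DTI-ALPS Indices, Brain Age Differences, and Aging-Trajectory Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the diffusion-tensor image analysis along the perivascular
    space (DTI-ALPS) index of glymphatic clearance from diffusion-weighted MRI,
    derives brain-predicted age differences (brain-PAD) from per-structure
    predicted-age tables, composites neuropsychological domain T-scores with the
    asymptomatic-neurocognitive-impairment rule, and runs the trajectory
    statistics that link them: assumption-gated two-group comparisons, linear
    aging-trajectory regressions, tests for equality of regression slopes
    between groups, sex-controlled partial correlations, and Benjamini-Hochberg
    false-discovery-rate control. Includes a synthetic diffusion-weighted
    phantom and cohort generator so that every stage of the pipeline can be
    exercised and validated end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
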