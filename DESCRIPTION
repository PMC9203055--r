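Package: optotower
Title: Sub-Trial Optogenetic Inactivation Analysis for the Accumulating-Towers Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how brief, spatially defined optogenetic
    inactivation of dorsal cortical areas changes the temporal weighting of
    pulsatile sensory evidence on choice in a virtual-reality
    accumulating-towers task, and to estimate cortical intrinsic timescales
    from widefield calcium imaging. Includes a synthetic cohort and trace
    generator with known ground truth, laser-aligned time-binned mixed-effects
    logistic regression of choice with shuffle nulls and false-discovery-rate
    control, psychometric and spatial evidence-weighting analyses with
    bootstrap inference, a ridge-penalized linear encoding model of ROI
    fluorescence with autoregressive and coupling terms, and exponential-decay
    estimation of intrinsic timescales from autoregressive coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    jsonlite,
    lme4,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
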