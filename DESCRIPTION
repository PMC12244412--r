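Package: cuedreach
Title: Trial-Based Analysis of Cued-Reaching Behavior, Striatal Units and
    Dopamine Photometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing head-fixed cued-reaching experiments in
    which a brief sensory cue predicts food-pellet availability. Implements
    signal-detection behavioral metrics (d-prime with dual false-alarm
    windows, learning stages, within-session learning flags), the
    three-trial-sequence bootstrap that quantifies outcome- and
    context-dependent trial-to-trial changes in reach rates, putative
    striatal-unit classification and peri-event analyses, a linear-link
    event-kernel GLM with an elastic-net regularization sweep, two-group
    clustering of post-outcome kernels, a rank-R Kruskal-tensor multinomial
    regression over neurons x time x conditions with a joint-loading
    solution-selection penalty, population decoding with shuffle controls,
    and demodulation of amplitude-modulated fiber-photometry signals via
    multitaper spectral power and rolling z-scores. A synthetic-data module
    generates behavioral sessions, spike trains and photometry traces with
    planted, recoverable structure so every analysis stage can be validated
    end to end without raw experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    lme4,
    lmerTest,
    MASS,
    Matrix,
    signal,
    stats,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
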