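Package: earp3
Title: Auditory Oddball P3 Analysis for Around-the-Ear EEG Recorded Across a Workday
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse day-long mobile ear-EEG (cEEGrid)
    auditory oddball sessions. Provides oddball schedule generation (rapid and
    sporadic variants), a synthetic-session generator (stimulus-locked ERPs on a
    1/f background, gyroscope movement states, behavioural responses from
    generative mixed models), continuous-data cleaning (zero-phase windowed-sinc
    FIR filters, flatline/amplitude/spectral channel rejection, artifact
    subspace reconstruction, spherical-spline interpolation), stimulus-locked
    epoching with joint-probability rejection and P3 window scoring on the
    vertical bipolar cEEGrid channel, gyroscope displacement thresholds and
    movement categorisation, and mixed-model inference (reaction-time and
    accuracy GLMMs, ERP LMM, Wald chi-square tests, likelihood-ratio model
    comparison, repeated-measures ANOVA with generalized eta squared).
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
    lme4,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
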