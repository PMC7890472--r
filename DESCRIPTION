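Package: dyadwarp
Title: Dyadic Nonverbal Coordination from Wearable Motion Sensors via
    Dynamic Time Warping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies interviewer-interviewee nonverbal coordination from
    body-worn gyroscope streams. Implements the four-step screening of raw
    120 Hz sensor data (out-of-range removal, cross-device alignment,
    down-sampling to 5 Hz, per-axis z-scoring), dynamic time warping with
    the Rabiner-Juang step-pattern taxonomy, inverted path-averaged
    coordination scores per body part with a missing-part aggregation rule,
    and the accompanying statistical layer (veracity-judgement coding,
    contingency tables with phi/Cramer's V, random-intercept mixed models of
    coordination on task difficulty with Bonferroni-corrected contrasts, and
    a 3x3 mixed ANOVA with partial eta squared). A synthetic dyadic-motion
    generator with known coupling ground truth makes every stage testable
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    lmerTest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
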