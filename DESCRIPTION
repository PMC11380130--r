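Package: gastrogaze
Title: Disgust Avoidance and Gastric Rhythm Analysis from Eye Tracking and Electrogastrography
Version: 0.1.0
Authors@R:
    person("gastrogaze", "developers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two physiological readouts of disgust:
    oculomotor avoidance in a preferential-looking task (area-of-interest
    dwell times from gaze recordings) and gastric dysrhythmia from
    multi-channel electrogastrography (Hampel and zero-phase Butterworth
    filtering in cycles-per-minute units, ICA-based component screening by
    normogastric signal-to-noise ratio, Hann/FFT band-power summaries, and a
    log-ratio gastric disgust index). Includes seeded synthetic-cohort
    generators with known ground truth for every stage, questionnaire
    scoring for four disgust-sensitivity instruments, a mixed-effects
    candidate-model ledger with AIC/BIC differences, and pairwise-complete
    correlation matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
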