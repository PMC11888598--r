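Package: socattn
Title: Multi-Dimensional Social Relationships and Social Attention in Primate Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking multi-dimensional social relationships
    (aggression, grooming, proximity) to social attention in a small primate
    group. Converts directed behavioral event logs into dichotomous (+1/-1)
    interaction score matrices, extracts saccadic response times from 1 kHz eye
    traces by joint velocity/acceleration thresholds, computes drifting-time and
    distractor-bias attention statistics from a congruent/incongruent visual
    orienting task, fits social (SEI) and individual (IEI) engagement indices by
    exhaustive weight grid search against distractor biases, and quantifies
    robustness via image-withdrawal resampling and saline/oxytocin condition
    contrasts. Includes a synthetic-study generator with known ground truth so
    every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
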