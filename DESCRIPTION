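Package: oculodyn
Title: Concurrent Pupillometry and Microsaccade Analysis for Effortful Listening Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing concurrently recorded pupil dilation and
    microsaccade data from speech-in-noise listening experiments. Provides a
    synthetic binocular eye-tracking data generator with known ground truth,
    readers and writers for an EyeLink-ASC-style text dialect, peristimulus
    epoching, the standard pupillometry preprocessing chain (fixation-break and
    blink masking, sparse-epoch rejection, linear interpolation, outlier trial
    removal, per-participant z-scoring, baseline correction), binocular
    velocity-threshold microsaccade detection with causal-kernel rate
    estimation, participant-level bootstrap significance masks for condition
    differences, and a simulator of the one-up-one-down adaptive
    speech-reception-threshold procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
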