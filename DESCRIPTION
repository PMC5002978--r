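Package: proseqhs
Title: Genome-Wide Analysis of Nascent Transcription During Heat Shock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for strand-specific, base-resolution PRO-seq
    data across heat-shock time courses: invariant-gene-set normalization,
    negative-binomial differential transcription with elongation-limited
    gene-body windows, an upstream-ratio filter against run-through
    transcription artifacts, promoter-proximal pausing quantification
    (pause-window detection, pausing index, Fisher's exact paused
    classification), composite metagene profiles with subsampling confidence
    bands, and transcription-factor peak-to-TSS binding statistics. Includes
    a synthetic-data generator with known ground truth for validating every
    stage.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
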