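Package: emrqc
Title: Standard-Compliance Testing for TCM Outpatient Electronic Medical Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A rules engine for conformance testing of Traditional Chinese
    Medicine (TCM) outpatient electronic medical records against health
    information standards. Checks per-record mandatory-item completeness and
    terminology code-range membership, computes batch-level integrity, coding
    and total scores, grades each record on a cumulative 0-5 star scheme, and
    emits machine- and human-readable conformance reports. Includes a
    synthetic record-batch generator with exact ground truth for testing
    assessment pipelines without real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
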