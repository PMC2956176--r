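Package: cancerhx
Title: Rule-Based Cancer History Classification from Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies free-text history-and-physical reports from mesothelioma
    patients for personal history of ancillary (non-mesothelioma) cancer and
    family history of any cancer. Cancer mentions are captured as seven-slot
    semantic frames built by either of two interchangeable rule engines: a
    hot-spot plus variable-size bi-directional window search, or a
    ConText-style trigger/scope engine driven by the same domain lexicon.
    Includes report/section/sentence parsing with subjective-section filtering,
    reference resolution of generic disease mentions, evaluation against gold
    labels (accuracy, precision, recall, F-measure), inter-annotator agreement
    statistics (observed and specific agreement, Cohen's kappa), and a seeded
    generator of synthetic clinical-note corpora with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
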