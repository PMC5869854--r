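Package: robscreen
Title: Automated Ascertainment of Risk-of-Bias Reporting in Full-Text
    Animal Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pattern-based detection of whether full-text manuscripts
    describing in vivo experiments report randomization of animals to
    groups, blinded assessment of outcome, and a sample size calculation.
    Ships an editable seed lexicon of inclusion and exclusion regular
    expressions, produces auditable true/false calls with evidence
    snippets, and evaluates them against manual gold-standard annotation
    with sensitivity, specificity, accuracy and exact (Clopper-Pearson)
    binomial confidence intervals. Also summarises reporting prevalence by
    corpus, journal and time epoch with least-squares trend fitting,
    reconstructs confusion matrices from published summary statistics, and
    generates deterministic synthetic methods-section corpora with known
    gold labels for offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
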