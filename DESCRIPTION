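Package: pktem
Title: Rule-Based Therapy-Efficacy Modeling from Tumor Pharmacokinetic Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores tumor gene expression against a composite normal-tissue
    reference using robust (median/MAD) Z-scores, evaluates administered
    therapies against a drug-gene pharmacokinetic knowledge base with a set
    of named efficacy rules (drug export, import, metabolism, target, and
    their combinations), classifies patients as high- or low-risk, and
    validates classifications with per-cancer and pan-cancer Cox survival
    models, DerSimonian-Laird random-effects meta-analysis, threshold
    sweeps, and repeated cross-validation. Includes a synthetic survival
    cohort generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
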