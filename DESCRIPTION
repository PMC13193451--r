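Package: sctcea
Title: Cost-Utility Analysis of Stem Cell Therapy for Ischemic Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state Markov cohort model (functional independence,
    disability, death on the modified Rankin Scale) for the cost-utility
    analysis of stem cell therapy versus standard of care in acute and
    subacute ischemic stroke, from the Japanese public health payer and
    combined healthcare plus long-term-care payer perspectives. Includes
    Mantel-Haenszel / DerSimonian-Laird risk-ratio pooling for the efficacy
    inputs, per-state hospitalization and long-term-care cost construction,
    discounted cost and QALY accumulation over a 10-year horizon, inversion
    of the incremental cost-effectiveness ratio to a threshold therapy
    price at a reference willingness-to-pay, one-way deterministic
    sensitivity analysis (tornado records), probabilistic sensitivity
    analysis, and synthetic-data generators that make every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
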