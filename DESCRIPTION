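Package: ivasa
Title: In-Silico Intravenous Alcohol Self-Administration Laboratory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale virtual laboratory for progressive-ratio intravenous
    alcohol self-administration experiments. Simulates breath alcohol
    concentration (BrAC) of a participant under a two-compartment
    Michaelis-Menten pharmacokinetic model, a clamp controller that enforces
    prescribed BrAC dynamics (+13 mg/dL reward ramps over 3 min, -0.8 mg/dL/min
    inter-reward decline, 180 mg/dL safety gate) within pump constraints, a
    progressive-ratio operant session engine with an adaptive constant-attention
    task, and a softmax behavioral agent whose positive reinforcement can be
    attenuated by a drug-level parameter. Includes the matching clinical-trial
    machinery: genotype-enriched synthetic cohorts, stratified permuted-block
    randomization, two-session trials, and endpoint analysis (cumulative work
    for alcohol/saline, pooled-variance t tests, Cohen's d with confidence
    intervals, correlations, slope-based subjective measures, and the
    intention-to-treat imputation rule), so that printed trial statistics can
    be reproduced from summary data and new drug-effect hypotheses screened
    in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
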