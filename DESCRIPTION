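Package: nephroCEA
Title: Cost-Effectiveness of Renin-Angiotensin-System Blockade Against
    Diabetic Nephropathy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A lifetime Markov cohort model of diabetic nephropathy
    progression (normoalbuminuria, microalbuminuria, macroalbuminuria,
    end-stage renal disease, death) in newly diagnosed type 2 diabetes,
    used to compare treating all patients with an ACE inhibitor (or ARB)
    at diagnosis against annual screening for micro- or macroalbuminuria
    from a health-insurance perspective. Provides base-case cost-utility
    evaluation with half-cycle correction and differential discounting,
    incremental comparison with dominance and extended-dominance
    classification, one-way sensitivity analysis over published parameter
    ranges, breakeven threshold search on the annual drug cost, and
    probabilistic sensitivity analysis (beta/gamma/Dirichlet sampling,
    net monetary benefit, cost-effectiveness acceptability curves). A
    deterministic Gompertz-Makeham module synthesises the age-specific
    background mortality and age-dependent health-care expenditure inputs
    normally taken from national statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
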