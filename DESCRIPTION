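Package: statinCEA
Title: Markov Cohort Cost-Effectiveness of Statin Primary Prevention
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A Markov cohort state-transition model of primary-prevention
    statin therapy for atherosclerotic cardiovascular disease. Converts age-
    and sex-specific cause-of-death life tables into annual probabilities of
    fatal and non-fatal coronary and cerebrovascular events, calibrates them
    to a target 10-year combined-endpoint risk at a chosen treatment-start
    age, and runs an annual-cycle cohort model (deterministic expectation
    plus a microsimulation bootstrap for confidence intervals) to age 99.
    Computes discounted quality-adjusted life years, incremental
    cost-effectiveness ratios, five-year numbers needed to treat, avoided
    event costs, budget impact and life-expectancy gains across grids of
    risk thresholds and treatment-start ages, with a synthetic-data
    generator so the whole pipeline runs without external mortality data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: graphics, stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
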