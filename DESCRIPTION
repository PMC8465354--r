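Package: ethnoindex
Title: Quantitative Ethnobotany Indices for Medicinal-Plant Surveys
Version: 0.1.0
Authors@R:
    person("Kupwara", "Analysis Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Data model, consensus indices and association tests for
    quantitative ethnobotanical surveys. Implements the use value (UV),
    use frequency (Fq), family use value (FUV), informant consensus
    factor (ICF), per-village relative frequency (Rf) and relative
    importance (RI) indices; maps free-text ailments onto fifteen disease
    categories; runs Pearson chi-square association tests of traditional
    knowledge against informant demographics and age-knowledge
    regressions; and ships both a transcribed aggregate survey of 107
    Himalayan medicinal taxa and a Dirichlet-multinomial interview
    simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
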