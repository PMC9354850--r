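Package: infodemix
Title: Infodemiology Analytics for Government Social-Media Post Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how government social-media channels
    communicate during public-health emergencies. Implements the Single
    Tweets Communication Index (STCI) for scoring per-post communication
    power from read and like counts, cross-account duplicated-content
    ("independence") matrices with valued network density, Ochiai-coefficient
    co-word networks built from post titles, rule-based content typing,
    temporal posting profiles, and Pearson correlation of posting volume
    against an epidemic curve. A synthetic-corpus generator plants known
    correlation, duplication, posting-hour and content-type structure so
    every analysis stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
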