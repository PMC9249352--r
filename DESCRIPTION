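Package: birfit
Title: Biphasic Exponential Modelling of Break-Induced Replication Efficiency
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the efficiency of ectopic break-induced replication (BIR)
    as a function of the length of DNA to be synthesized to the telomere.
    Fits single and two-segment exponential decay laws by nonlinear least
    squares, scans candidate breakpoints and selects among them by the Akaike
    Information Criterion, and derives the mechanistic parameters of a per-
    kilobase survival model: the initiation probability k, the per-kb
    continuation probabilities p1 and p2 of the low- and high-processivity
    phases, and the threshold length T at which the phases switch. Includes
    a mechanistic per-kb chain simulator of transformation experiments for
    power and parameter-recovery studies, distance arithmetic for reciprocal
    translocations that exchange terminal chromosome segments, and the exact
    contingency-table and two-sample tests used on BIR product classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
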