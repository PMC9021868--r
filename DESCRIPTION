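Package: chillreq
Title: Chilling and Heat Requirements of Fruit-Tree Cultivars from
    Winter Temperatures and Bloom Dates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the endodormancy-to-ecodormancy transition date and
    the chilling and heat requirements of temperate fruit-tree cultivars
    from hourly winter temperature records and full-bloom (F50) dates.
    Implements four break-date estimators (forcing-test bud-weight
    criterion, moving-window temperature/bloom correlation, partial least
    squares phase delineation, and externally observed biomarker dates),
    three chill-accumulation models (Dynamic chill portions, Utah chill
    units, Weinberger chilling hours) plus growing degree hours, cultivar
    classification by requirement bands, and Bland-Altman agreement
    analysis between methods. A seed-deterministic synthetic generator
    produces multi-year hourly weather and phenology records from a
    sequential chill-then-heat ground truth for validation and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
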