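Package: icepools
Title: Intracellular Nutrient Pool Estimation for Sea-Ice Algal Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates intracellular (IC) nitrate+nitrite and silicic acid
    pools stored by bottom-ice algal communities from field measurements made
    with three complementary sampling techniques (bottom-ice scrape samples,
    filtered-seawater-diluted core melts, and bulk ice melts). Provides the
    physical relations for brine salinity and conservative dilution lines,
    chlorophyll-a fluorometry and melt-dilution corrections, the full
    chain from blank-corrected hot-water extraction filtrate to chl-specific,
    bottom-ice, per-cell-volume and per-cell IC nutrient quantities,
    standardized major axis regression for inferring differential retention of
    IC pools during bulk melt, tidally forced time-series analysis of
    detrended IC residuals, and a synthetic campaign generator that emulates a
    declining spring bloom under spring-neap tidal forcing so the whole
    pipeline is testable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
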