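Package: transbound
Title: Transboundary Classification and Fisheries Accounting for Exploited Marine Species
Version: 0.1.0
Authors@R: person("Transbound", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies exploited marine species as transboundary or discrete
    per Exclusive Economic Zone (EEZ) from gridded multi-source presence layers
    and an EEZ adjacency graph, using a three-criteria procedure (neighboring
    EEZs with country/territory collapsing rules, four-source presence
    consensus with a catch-positivity filter, and a pairwise Area Index with a
    25 percent shared-distribution threshold). Categorizes per-stock catch
    trends as increasing, constant or decreasing from annual catch series, and
    accounts catch and ex-vessel revenue by stock class, country and UN
    sub-region with CPI standardization, including per-km2 weighting. Ships a
    fully synthetic world generator (EEZ mosaic with known adjacency, species
    ranges with controllable per-EEZ shares, four presence sources with a
    tunable agreement rate, catch and price series with known trend categories)
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
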