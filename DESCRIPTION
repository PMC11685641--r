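Package: sorisk
Title: Southern Ocean Microplastic Hotspot Risk Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Grids heterogeneous biotic (krill net samples, chlorophyll-a rasters),
    abiotic (sea surface temperature and pH trends), and human-activity (ship
    traffic, terrestrial facilities) data onto a common 9 degree x 3 degree
    circumpolar grid, ranks each layer on a discrete 1-5 concern scale, and
    composes baseline, interaction, and combined risk maps locating where
    potential local microplastic emissions are most likely to interact with
    biota and existing abiotic stresses. Includes a zero-assimilating geometric
    mean for zero-inflated abundance data, a classical additive X11-style
    seasonal-trend decomposition with per-cell linear trend inference, facility
    and ship-traffic person-day emission proxies with inverse-square
    effective-population smoothing, and a synthetic-data generator that
    emulates the statistical structure of the source datasets so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
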