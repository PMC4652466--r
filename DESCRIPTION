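Package: microclubs
Title: Bacterial Social Clubs, Club Leaders and Rival Clubs from OTU
    Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds significance-masked Pearson co-occurrence networks from
    OTU (operational taxonomic unit) abundance tables, detects groups of
    co-occurring taxa ("clubs") with a from-scratch Markov clustering
    implementation that also extracts attractor nodes ("club leaders"),
    finds anti-correlated club pairs ("rival clubs") via a two-phase
    clustering of the absolute-value and positive-only networks, and renders
    force-directed network diagrams and club-ordered correlation heat maps.
    Includes a latent-factor synthetic community generator with planted
    clubs, rivals and leaders so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
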