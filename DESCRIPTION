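Package: moltwave
Title: Flight-Feather Molt Series, Wave, and Duration Inference from
    Specimen Snapshots
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the rules of flight-feather replacement from
    cross-sectional molt scores of museum specimens: per-feather score
    parsing and validation, nodal/terminal and pairwise
    replacement-direction annotation, raw and iterated molt summary
    tables with cross-series boundary reassignment, exact binomial sign
    tests for replacement direction, detection of stepwise molt waves,
    growth-band rate estimation, and molt-duration estimation via
    d = l / (r * y).  Includes a continuous-time stochastic simulator of
    feather replacement with molt arrests and the resume-plus-restart
    rule that generates stepwise molt, emitting synthetic specimen
    snapshots in the standard record format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
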