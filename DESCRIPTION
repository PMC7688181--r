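Package: opinionlattice
Title: Two-Population Opinion-Expression Dynamics on a Square Lattice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based model of public opinion expression in which
    consensus-seeking and reputation-seeking agents on a periodic square
    lattice decide synchronously, from the opinions voiced by their four
    von Neumann neighbours, whether to voice a fixed private attitude or
    remain silent. Provides exact limit-cycle detection on the behaviour
    configuration, the public-private opinion discrepancy index and its
    four equilibrium scenarios, silence-density and local-network-state
    observables, and a replicated density-sweep experiment harness with
    tidy per-run records, aggregate summaries, and command-line entry
    points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
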