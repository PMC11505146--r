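Package: cotlattice
Title: Chemical Organization Theory Analysis of Reaction Networks
Version: 0.1.0
Authors@R:
    person("cotlattice", "developers", email = "cotlattice@example.org",
           role = c("aut", "cre"))
Description: Enumerates the organizations (closed and self-maintaining
    subnetworks, possibly distributed over several compartments) of a
    biochemical reaction network, arranges them in a Hasse lattice and
    derives structural complexity parameters: number of organizations,
    lattice height and width, persistence, and compartmentalization
    statistics.  Reads SBML Level 2/3 models and a plain-text reaction
    dialect, ships the classic six-variable cell-cycle oscillator of
    Tyson (1991) as a built-in fixture, validates the enumeration
    against a brute-force oracle and against mass-action simulations,
    and provides a command-line interface for batch screens of model
    collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
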