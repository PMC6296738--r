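Package: herdsim
Title: Agent-Based Simulation of Cattle-Farm Structural Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An empirical-style agent-based model of structural change in a
    regional cattle-farming sector. Individual holdings hold herds of eight
    cattle types linked in a supply chain (service bulls, breeders, calves,
    finishers) and decide annually whether to expand, shrink or hold herd
    size. Four contested social mechanisms (succession, leisure farming,
    tourism diversification, industrialization) can be toggled on and off,
    and a pattern-oriented-modelling sweep over all sixteen mechanism
    combinations selects those that reproduce the "disappearing middle"
    polarization of farm sizes. Post-2019 trade scenarios (FTA, WTO, UTL)
    enter as permanent commodity price shocks. A synthetic census generator
    produces holding-level populations with configurable size-class,
    succession, leisure, tourism and manager-run shares, so the whole
    pipeline is testable without confidential census microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
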