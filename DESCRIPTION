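Package: rxnkinetics
Title: Reaction-Progress Kinetics from Simulated and Monitored Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale workbench for automated reaction-kinetics
    workflows. Integrates mass-action reaction networks (with empirical
    fractional-order rate laws) to concentration traces, renders them into
    noisy benchtop NMR and UV-Vis spectra on a sampling schedule, and
    recovers kinetic parameters through the standard analysis chain:
    baseline-corrected region integration, conversion computation,
    initial-rate and pseudo-first-order fits, second-order rate-constant
    regression, log-log reaction orders, variable time normalization
    analysis (VTNA), Hammett linear free-energy regression, and windowed
    plateau detection that terminates a monitored experiment and freezes
    it into a static, replayable protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    graphics,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
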