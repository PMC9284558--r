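Package: tempogate
Title: Compilation and Multi-Fidelity Simulation of DNA Strand-Displacement
    Temporal Logic Gates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and simulating chemical reaction networks
    (CRNs) that implement temporal logic in DNA strand-displacement circuits.
    A two-input temporal AND gate converts each input into a memory strand and
    uses cooperative hybridization to produce order-specific outputs, so that
    distinct output species report both the presence and the arrival order of
    the inputs. The package compiles such gates at three model fidelities
    (abstract mass-action, trimolecular strand-displacement with crosstalk,
    and an elementary-step model with toehold binding, dissociation, and
    mismatch-slowed branch migration), simulates them deterministically with
    an event-driven stiff Rosenbrock integrator or stochastically with the
    Gillespie algorithm, and provides the characterization scans used to
    study such circuits: truth-table evaluation, ON/OFF separation, input
    time-resolution scans, toehold-length surveys, rate-bias surveys, and
    crosstalk branch-migration-rate suppression scans. Plain-text CRN files,
    CSV trajectories, and a minimal SBML export are supported.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
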