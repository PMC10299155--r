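Package: smg4
Title: Single-Molecule Kinetics of Protein Binding to G-Quadruplex DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule TIRF microscopy
    experiments probing the binding of G-quadruplex recognition proteins to
    surface-tethered G4 DNA. Provides a synthetic-data generator with known
    ground truth (two- and three-state Markov binding trajectories, TIRF
    movie stacks, FRET donor/acceptor traces, mass-photometry event lists
    and EMSA titrations), spot detection and trace extraction from movie
    stacks, trajectory quality control, Gaussian hidden Markov model
    idealization with model selection, dwell-time extraction and
    exponential fitting with left truncation, and the derived binding
    constants (association and dissociation rate constants, bound-state
    lifetime and equilibrium dissociation constant) with propagated
    uncertainties. Companion modules compute FRET efficiency histograms
    with donor-leakage correction, mass-photometry calibration and
    Gaussian-mixture mass histograms with stoichiometry assignment, and
    equilibrium binding isotherm fits with dye-labeling efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
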