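Package: cavgating
Title: Simulation and Analysis of Whole-Cell Voltage-Clamp Gating for
    L-Type Calcium Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the voltage-dependent gating of
    Cav1.3-style L-type calcium channels from whole-cell patch-clamp data.
    Provides a deterministic Hodgkin-Huxley-type conductance simulator for
    voltage-step protocols (current-voltage families, 5-s steady-state
    inactivation and inactivation time-course protocols) with ohmic leak,
    capacitive transients and Gaussian recording noise; a synthetic-cohort
    generator with between-cell parameter variability; trace preprocessing
    (liquid-junction-potential correction, offline and P/4 leak subtraction,
    peak extraction, capacitance normalization, amplitude-based quality
    control); Boltzmann-based parameter estimation (I-V fits, conductance-
    voltage activation fits, steady-state inactivation fits with a
    non-inactivating plateau, r-value inactivation kinetics); and cohort
    statistics (mean +/- SEM summaries, Student's t-tests, one-way ANOVA with
    Bonferroni post-hoc comparisons, publication-style tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
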