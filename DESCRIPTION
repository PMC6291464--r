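Package: plinet
Title: Phase-Lag-Index Functional Networks from Multichannel EEG
Version: 0.1.0
Authors@R:
    person("plinet", "maintainers", email = "plinet@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for EEG working-memory
    experiments based on phase synchronization networks. Generates
    multichannel recordings with planted band-specific phase coupling at
    known target phase lag index (PLI), preprocesses them (zero-phase FIR
    band-pass filtering, epoching, amplitude-based artifact rejection,
    edge trimming), estimates PLI connectivity matrices from Hilbert
    instantaneous phases, computes weighted undirected network topology
    (Onnela clustering coefficient, characteristic path length,
    small-world coefficient against weight-shuffled surrogates), and runs
    a nonparametric statistics battery (rank partial correlation,
    Friedman, Wilcoxon signed-rank, Mann-Whitney U, Benjamini-Hochberg
    FDR control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    rhdf5
Config/testthat/edition: 3
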