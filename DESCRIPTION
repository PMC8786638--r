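Package: roboprey
Title: Robotic-Predator Arena Simulation, Multi-Species Tracking, and
    Information-Flow Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ethorobotics experiments in which a biologically
    inspired robotic predator interacts with mixed groups of mosquitofish and
    tadpoles in a circular arena. Provides an agent-based simulator of the
    arena with the robot's three-tier interactive attack controller and
    configurable directed behavioural coupling between species; a synthetic
    video renderer; a multi-species blob tracker combining multiple
    thresholding, optimal (Hungarian) assignment and constant-velocity Kalman
    prediction for missed detections; group-behaviour metrics (furthest
    neighbour distance, inter-individual distance, distance swam, turning
    rate, concentric-region occupancy, Fulton's condition factor); and
    symbolic transfer-entropy estimation between species with a
    trial-shuffling permutation significance test. A command-line interface
    chains the stages into a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    graphics,
    data.table,
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
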