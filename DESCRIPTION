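Package: cervidyn
Title: Whole-Body Musculoskeletal Simulation of Cervical Spine Loading
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Rigid-body musculoskeletal simulation for the analysis of cervical
    spine loading. Provides a full-body segment/joint model with
    coordinate-coupler constraints, a scapula-clavicular joint driven by humeral
    elevation (scapulohumeral rhythm), Hill-type neck musculature with
    population-specific strength scaling, forward-dynamics verification
    protocols (workless-constraint audit, passive range-of-motion loading,
    maximal isometric moments), and a marker-based inverse pipeline (inverse
    kinematics, inverse dynamics, joint-reaction analysis, static-optimization
    activation estimation, EMG envelope processing). Includes synthetic-data
    generators with known ground truth and readers/writers for TRC, STO/MOT and
    C3D motion files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    yaml,
    jsonlite,
    signal,
    deSolve,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
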