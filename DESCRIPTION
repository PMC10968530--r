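Package: iwire
Title: Contractility and Elasticity Analysis for Probe-Loaded Engineered
    Cardiac Tissue Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for engineered cardiac tissue constructs
    (ECTCs) suspended between two anchor wires and loaded transversely by a
    calibrated flexible probe (the I-Wire configuration). Converts probe-tip
    movies or centroid traces into probe force, per-beat systolic, diastolic
    and developed force, axial fiber tension, Frank-Starling force-tension
    curves, beating-rate chronotropy, and Young's modulus from diastolic
    stretch-stress curves. Includes a ground-truth-known synthetic recording
    generator (twitching string model with length-dependent activation,
    linear-spring probe, acquisition noise, optional rendered image stacks)
    so that every stage of the pipeline is testable without raw optical data,
    plus study-level orchestration with paired and unpaired comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
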