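Package: fishstim
Title: Virtual Fish Motion Stimuli and Social Approach Assay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constructing systematically manipulated virtual-fish
    motion stimuli from tracked swimming trajectories and for quantifying
    social approach (shoaling) behaviour in small fish. Converts multi-point
    body-midline tracks into skeletal animations in the BioVision Hierarchy
    (BVH) format via Euler-angle decomposition of the segment chain, applies
    factorial stimulus manipulations (greyscale colour, pressed body shape,
    locomotion removal, body-axis motion removal, static frames, loop
    concatenation), scores zone-occupancy assays with baseline exclusion and
    difference scores, and analyses the resulting mixed designs with split-plot
    ANOVA, a multisample sphericity test, Huynh-Feldt correction, simple main
    effects, and Ryan's stepwise post-hoc procedure. Includes seeded synthetic
    generators for swimming trajectories and assay occupancy traces so the full
    pipeline is reproducible without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tibble,
    withr,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
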