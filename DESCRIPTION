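Package: lipomech
Title: Phospholipid Unsaturation and Muscle-Cell Membrane Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate the polyunsaturated fatty-acid content of membrane
    phospholipids to the mechanical resilience of muscle cells. Annotates
    phosphatidylcholine species from exact masses and summarizes them as
    double-bond indexes, DHA/AA ratios and a cross-sample PCA; extracts
    vacuole-like-dilation (VLD) formation kinetics, cell-breakage calls and
    surface-expansion metrics from fluorescence time-lapse traces and image
    stacks recorded under osmotic downshock; post-processes coarse-grained
    membrane trajectories under imposed surface extension (acyl-chain tilt
    angle and extension distributions, Kirkwood-Irving surface tension from
    pressure-tensor series); and generates every input synthetically with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
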