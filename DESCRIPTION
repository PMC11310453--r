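Package: HDXdelta
Title: Differential Analysis of Hydrogen-Deuterium Exchange Mass Spectrometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of peptide-level hydrogen-deuterium exchange mass
    spectrometry (HDX-MS) experiments comparing multiple protein states. Reads
    HDExaminer-style long-format exports, matches peptides across states, time
    points and replicates, identifies significant deuterium-uptake differences
    with a hybrid test combining per-peptide Welch's t-tests and a dataset-wide
    critical interval, computes publication summary statistics (coverage,
    redundancy, back exchange), and produces volcano plots, Woods plots, robot
    plots, residue-level heatmaps, significant-peptide maps and PyMOL coloring
    scripts. Includes a synthetic-export generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
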