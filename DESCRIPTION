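Package: homtm
Title: Proteoform Pair Identification from Top-Down Homogeneous Multiplexed
    Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and quantifies pairs of modified proteoforms of a
    known protein from a single deconvoluted top-down homogeneous multiplexed
    tandem mass (HomMTM) spectrum. The spectrum, the protein sequence and a
    table of expected post-translational modifications are converted into a
    layered vertex-capacitated graph whose source-to-sink paths are proteoform
    candidates; the minimum-error 2-splittable flow problem is then solved
    exactly by candidate-packing enumeration and dynamic-programming routing,
    yielding two proteoforms with integer relative abundances. Includes an
    msalign-style spectrum reader, a synthetic HomMTM spectrum simulator with
    ground truth, brute-force solver oracles, and a batch identification
    driver with a command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
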