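Package: fticrms
Title: Untargeted FTICR-MS Metabolome Profiling and Molecular Networking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for direct-injection Fourier-transform ion
    cyclotron resonance mass spectrometry (FTICR-MS) peak lists from plant
    extracts: peak filtering and cross-sample alignment, internal mass
    recalibration on CH2 homologous series, CHONSP molecular-formula
    assignment from exact mass, van Krevelen compound-class annotation,
    mass-difference transformation networks with first-neighbor mining
    around reference compounds, reference-library matching with isomer
    collapse, class-abundance principal component analysis, and a
    ground-truth-annotated synthetic peak-list generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
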