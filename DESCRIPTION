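Package: mitoquant
Title: Quantification of Mitophagy, Mitochondrial Quality and Bioenergetics
    from Fluorescence Images and Flux Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible, fully scripted re-implementation of the
    image- and trace-quantification procedures used in high-content studies
    of mitochondrial turnover: mito-QC mitolysosome counting and mitophagy
    flux, classification of individualized depolarized mitochondria from
    TMRE/MitoTracker Green stacks, mitochondrial mass, mitophagosome and
    lysosome "touching" colocalization counts, peripheral-lysosome
    distribution statistics, nuclear-translocation intensity, STED
    line-profile cristae density, and mito-stress-test respirometry
    parameters.  A seeded synthetic-field generator provides ground truth
    for every assay so the whole pipeline is testable without raw
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
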