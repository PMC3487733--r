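Package: barcodiv
Title: DNA-Barcode Biodiversity Assessment for Hyperdiverse Arthropod Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing biodiversity from COI DNA-barcode surveys of
    hyperdiverse arthropod communities. Provides sequence quality grading,
    delineation of molecular operational taxonomic units (MOTUs) by an
    absolute nucleotide-change threshold, specimen-based accumulation curves
    with terminal-slope completeness diagnostics, Chao1 richness estimation
    with standard errors, and community-structure analysis (Hellinger
    transformation, Bray-Curtis dissimilarity, complete-linkage dendrograms,
    ANOSIM). A synthetic-community generator with known ground truth supports
    end-to-end validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
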