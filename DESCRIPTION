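Package: loopMDS
Title: DNA-Loop Calling from Hi-C Contact Maps by Classical Multidimensional Scaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a planar "tentative chromosome structure" from binned
    Hi-C contact frequencies by distance-decay weighting, inverse-contact
    distance transformation and classical (Torgerson) multidimensional scaling,
    then calls DNA-loop regions from the smoothed profile of consecutive-bin
    step distances. Includes vanilla-coverage normalization, readers for sparse
    contact triplets and BED/narrowPeak peak intervals, base-pair overlap
    enrichment statistics against peak sets (observed-versus-expected odds
    ratio with an exact or chi-square test), gene counting within loops, and a
    seeded synthetic contact-map generator with planted loops for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
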