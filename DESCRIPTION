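Package: divshift
Title: Birth-Death Diversification-Rate Shifts and Clade Richness Envelopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects shifts in diversification rate on time-calibrated
    phylogenies whose tips carry extant species-richness counts. Implements
    the combined phylogenetic and taxonomic birth-death likelihood for
    chronograms with unresolved terminal clades, a stepwise-AIC search over
    rate-shift points (forward addition and backward elimination), and
    Magallon-Sanderson expected-richness confidence envelopes for
    classifying clades as exceptionally species-rich or species-poor given
    their age. Includes forward birth-death simulators for synthetic
    chronograms and clade sizes, backbone collapse to unresolved-clade
    datasets, and a bundled cichlid divergence-time and richness dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
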