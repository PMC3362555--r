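Package: minibar
Title: Sliding-Window Selection of DNA Mini-Barcodes for Degraded DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Objective selection of the shortest informative mini-barcode
    region of a marker gene from a species-labelled reference alignment,
    using a sliding-window analysis that scores every candidate window by
    the proportion of zero non-conspecific pairwise distances and by
    clade congruence between window neighbour-joining trees and the
    full-alignment tree. Includes degenerate in-silico PCR and primer
    specificity screening, a metabarcoding amplicon pipeline
    (dereplication, length/primer/copy-number filtering, distance-based
    assignment to a reference library, single-linkage detection of novel
    clades), and seeded simulators of reference libraries and degraded
    amplicon reads so the whole workflow can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
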