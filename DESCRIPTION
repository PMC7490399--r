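Package: ForamActivity
Title: Quantifying Anaerobic Foraminifera Activity from Sediment Metatranscriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: A tested pipeline for estimating the transcriptional activity of
    benthic Foraminifera (and other microbial eukaryote groups) in marine
    sediment metatranscriptomes. Provides six-frame ORF prediction on
    assembled contigs, thresholded best-hit homology annotation with taxon
    and KOG labels, contaminant-genus filtering, a presence/absence
    unique-ORF activity statistic robust to single-primer isothermal
    amplification (SPIA) depth bias, greedy iterative seed extension of 18S
    rRNA barcodes with per-base coverage reporting, and community statistics
    (Bray-Curtis/Jaccard distances, ANOSIM permutation tests, UPGMA
    clustering). A synthetic-community generator with full ground truth makes
    every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    ape,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
biocViews: Metagenomics, Transcriptomics, Microbiome, Clustering, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
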