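Package: nucleoclass
Title: Discriminating Stable Nucleosomes Bearing Mutually Exclusive Histone Marks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end ChIP-Seq analysis of stable nucleosomes carrying one of
    two mutually exclusive chromatin marks. Provides read deduplication and
    depth normalization by down-sampling, NPS-style stable-nucleosome calling
    (3' read extension, wavelet or Gaussian denoising, Laplacian-of-Gaussian
    edge detection, Poisson enrichment testing, width/strand-ratio quality
    filters), strand-specific histone-modification overlap features,
    discriminatory k-mer motif features elicited on a withheld discovery
    partition, balanced random-forest classification with out-of-bag
    evaluation, Gini importance and permutation significance, and downstream
    satellite-repeat composition and occupancy analysis. A seeded synthetic
    data generator emulates the read pileup, duplicate, depth and
    co-localization structure the analysis assumes, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
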