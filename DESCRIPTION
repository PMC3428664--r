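Package: homeocure
Title: Homoeologue Expression Apportioning in Allopolyploids by Iterative
    Reference Curing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discriminates the contributions of homoeologous gene copies to
    an allopolyploid transcriptome from short mRNA-Seq reads. A consensus
    unigene reference is iteratively "cured" towards each diploid progenitor
    genome using split reads, an ungapped best-hit aligner with a mismatch
    cap, and quality-aware consensus calling. Base positions at which the two
    cured references differ are reported as inter-homoeologue polymorphisms
    (IHPs); polyploid reads are then apportioned between the two genome
    versions of each unigene, quantified as read counts and RPKM, and tested
    for differential homoeologue contribution with a paired quasi-Poisson
    generalised linear model and Benjamini-Hochberg adjustment. A synthetic
    allopolyploid transcriptome generator with known truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
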