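Package: cenevol
Title: Centromere Evolution, Methylation-Domain Phylogeny and Structural-Variant
    Polarization for Trio Genome Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of three related genome assemblies
    (two ingroup strains and an outgroup): clustering of centromeric satellite
    monomers and comparison of their evolutionary rates between acrocentric and
    non-acrocentric chromosomes, k-spectrum-kernel distances and UPGMA phylogeny
    of hyper- and hypomethylated centromeric domains, spectrum-kernel SVM
    discrimination of methylation domain classes, naive-Bayes Hi-C anchoring of
    orphan contigs with contact-peak placement, chained-alignment structural
    variant calling with outgroup polarization of insertions versus deletions,
    and regulatory statistics around transcription start sites carrying
    mid-sized insertions. Includes a synthetic trio-genome generator that
    plants every feature class with recorded ground truth so that each stage
    can be scored for parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    Matrix,
    kernlab,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
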