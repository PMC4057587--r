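Package: ncdphylo
Title: Compression-Based Alignment-Free Distances and Phylogenies for
    Genomes and Short-Read Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembly-free, alignment-free and parameter-free comparison of
    long genomic sequences and next-generation-sequencing read samples via
    compression-based distances: the compression dissimilarity measure
    C(xy)/(C(x)+C(y)), the conditional-compression distance
    (C(x|y)+C(y|x))/C(xy), and the normalized compression distance
    max(C(x|y),C(y|x))/max(C(x),C(y)).  Compressed sizes come from a
    pluggable backend registry whose built-in coder is an adaptive mixture
    of context models plus a repeat-match expert, driving an arithmetic
    coder over the nucleotide alphabet and supporting true conditional
    compression by model priming.
    Includes neighbor-joining tree reconstruction, outgroup rooting,
    Robinson-Foulds symmetric difference, leaf-label parsimony scoring of
    clustering trees against a true classification, a short-read simulator
    with coverage and error-model controls, a Jukes-Cantor genome evolver,
    and readers/writers for FASTA, FASTQ, PHYLIP distance matrices and
    Newick trees.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phytools,
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
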