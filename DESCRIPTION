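Package: mitosel
Title: Comparative Mitogenomics and Codon-Model Selection Pressure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of mitochondrial genomes:
    structural and compositional statistics of annotated mitogenomes
    (gene sizes, intergenic spacers and overlaps, start/stop codon
    tallies, strand partition, AT/GC skew, relative synonymous codon
    usage), maximum-likelihood codon substitution models with
    branch-specific dN/dS (one-ratio, two-ratio and free-ratio branch
    models with likelihood-ratio tests), root-to-tip omega aggregation,
    habitat-group comparison via the Mann-Whitney-Wilcoxon test, and
    phylogenetic independent contrasts of evolutionary rate against
    niche type.  A seed-deterministic codon-evolution simulator
    generates alignments with known branch-specific dN/dS so that every
    stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
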