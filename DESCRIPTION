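Package: codonbias
Title: Codon Usage Bias and Compositional Analysis of Protein-Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-gene codon usage bias indices for validated coding sequences:
    positional base composition and GC/AT skews, relative synonymous codon
    usage (RSCU), Wright's effective number of codons (ENC), frequency of
    optimal codons (Fop), and the relative codon bias score (RCBS) used as a
    gene-expression proxy. Cross-gene comparative analyses (codon-GC3s
    correlations, hierarchical clustering of RSCU profiles, ENC-GC3s
    relation), Kimura 2-parameter distances with neighbor-joining trees and
    bootstrap support, and synthetic-data generators for coding sequences
    with controllable synonymous codon usage and for alignments evolved
    under a two-parameter substitution model on a known tree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
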