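Package: MitoCircle
Title: Characterization of Circular Mitochondrial Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative characterization of animal
    mitochondrial genomes. Reads annotated mitogenomes from GenBank flat
    files or plain feature tables into a validated circular annotation
    object, and computes per-region nucleotide composition and strand
    asymmetry (AT/GC skew), circular gene overlap and intergenic spacer
    accounting, codon usage and relative synonymous codon usage (RSCU)
    under the invertebrate mitochondrial code, pairwise Ka/Ks by the
    Nei-Gojobori (1986) counting method with Jukes-Cantor correction, and
    signed circular gene-order comparison against ancestral arrangements,
    including a tandem duplication/random loss (TDRL) reachability test.
    A synthetic-mitogenome simulator generates annotated genomes and
    codon-evolved CDS panels with controlled composition, codon usage and
    dN/dS, so the whole pipeline can be exercised without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Genetics, Annotation, SequenceMatching, Phylogenetics
RoxygenNote: 7.3.3
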