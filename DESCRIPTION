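Package: TissueParalogs
Title: Tissue-Specific Gene Classification and Molecular Evolution of
    Duplicate Gene Pairs in an Allotetraploid Transcriptome
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Classifies genes as tissue-specific, common, or intermediate
    from a gene-by-tissue FPKM matrix; detects duplicate (paralog) gene
    pairs by all-vs-all coding-sequence similarity; builds codon-level
    alignments by global protein alignment and back-translation; estimates
    synonymous (Ks) and nonsynonymous (Ka) substitution rates per site with
    Nei-Gojobori (1986) pathway counting and Jukes-Cantor correction;
    computes codon usage bias as the frequency of optimal codons (Fop); and
    compares groups with rank-based tests. Includes a synthetic-data
    generator that plants known classification structure and evolves
    duplicate pairs at controlled synonymous divergence and dN/dS, and a
    pipeline that runs the full analysis from one configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, SequenceMatching, Genetics, Software
RoxygenNote: 7.3.3
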