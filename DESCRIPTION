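Package: amatox
Title: Mining and Molecular Evolution of Fungal Cyclic-Peptide Toxin Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genomic and phylogenetic analysis of the amanitin
    biosynthesis genes of lethal agarics (Amanita, Galerina, Lepiota).
    Mines MSDIN-family toxin precursor genes and prolyl oligopeptidase (POP)
    homologs from assembled contigs with a leader-peptide profile scan and a
    splice-aware aligner; links genotype to chemotype by computing elemental
    formulas and monoisotopic masses of cyclic core peptides (with amatoxin
    modifications) and matching them against MS1 peak lists at ppm tolerance;
    and assembles horizontal-gene-transfer evidence from gene-tree/species-tree
    conflict, approximately-unbiased (AU) topology tests via multiscale RELL
    bootstrap, duplication-loss versus duplication-transfer-loss
    reconciliation, and Nei-Gojobori (NG86) dN/dS and distance-ratio
    statistics. Includes seeded synthetic-data generators (planted toxin
    genes, trees with transfers, GTR+Gamma sequence evolution, noisy peak
    lists) so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    BiocGenerics,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
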