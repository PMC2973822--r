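Package: kircontent
Title: Gene-Content Population Genetics for KIR Loci and Their MHC Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic and molecular-evolution analyses for
    gene-content-variable killer-cell immunoglobulin-like receptor (KIR)
    loci and their MHC class I ligands. Provides presence/absence genotype
    and haplotype containers with TSV readers and writers, genotype-diversity
    rarefaction and bootstrap mean pairwise gene-content difference,
    gene-content linkage disequilibrium (pairing frequencies, Fisher exact
    tests, normalized association ratios), EM estimation of haplotype
    frequencies from unphased presence/absence genotypes, C1/C2/Bw4 epitope
    classification from MHC residues 76 and 80 with a binomial co-occurrence
    test, Sankoff parsimony counting of state changes on trees with exact
    per-transition ranges over most-parsimonious reconstructions, the ANDI
    (average number of distinct interactions) receptor-ligand statistic, and
    seeded synthetic-data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
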