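Package: hlafinemap
Title: Fine-Mapping Disease Associations in the HLA Region from Imputed
    Classical Alleles and Amino Acid Dosages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting case/control association signal in the major
    histocompatibility complex down to individual amino acid residues. Starting
    from imputed classical HLA allele genotype posteriors and an allele-to-peptide
    alignment, the package builds expected-copy (dosage) matrices for alleles and
    residues, runs marginal, conditional, omnibus and forward/backward stepwise
    logistic regression over residues, classical alleles and SNPs, tests whether
    residues out-explain chance tagging of classical alleles with a permutation
    null over allele-to-sequence assignments, quantifies selection stability by
    bootstrap resampling, and searches exhaustively for the best residue pairs
    and triples ranked by AIC. A synthetic cohort generator with cross-gene
    haplotype linkage disequilibrium and planted causal residues makes the whole
    pipeline testable without access to individual-level genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
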