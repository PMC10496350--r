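Package: fedhegwas
Title: Threshold Homomorphic Encryption and Federated GWAS for Binary Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Collaborative genomic analysis across multiple sites without
    sharing individual-level data. Implements threshold CKKS-style
    homomorphic encryption with additive secret-key sharing and collective
    decryption (a real single-modulus RLWE backend at small ring degree and
    a fast plaintext emulation with CKKS semantics), slot-packed encrypted
    matrix algebra (row/column expansions, shift-and-add row-row inner
    products, masking-based collaborative matrix inversion), and on top of
    it a federated score-test GWAS for binary phenotypes with IRLS null
    model fitting, secure meta-analysis of per-site score statistics, and a
    population-structured cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
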