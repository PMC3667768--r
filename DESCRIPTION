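Package: utrcoop
Title: Cooperativity Between RNA-Binding Proteins and MicroRNAs in 3'UTRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing cooperative interactions between RNA-binding
    protein (RBP) recognition motifs and microRNA seed-match sites in 3'UTRs.
    Implements conservation gating of consensus motifs by branch length score
    against shuffled-motif controls, positional localization profiles along
    3'UTRs, permutation-based co-localization calling of interacting miRNA
    families with three identity-shuffling null schemes and
    Benjamini-Hochberg FDR, transcript decay and site-conservation group
    comparisons, a secondary-structure rescue-count statistic under RBP-site
    masking (thermodynamic or maximum-pairing folding engines with a
    dinucleotide-preserving shuffle background), and local-alignment scoring
    of miRNA seed hybridization to reversed RBP motifs.  A synthetic-data
    generator with planted signal exercises the whole pipeline without any
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    jsonlite
Config/testthat/edition: 3
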