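Package: its2ss
Title: ITS2 Sequence-Structure Analysis for Discriminating Ampelomyces Mycoparasites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delimiting the fungal nuclear rDNA internal transcribed
    spacer region (ITS1-5.8S-ITS2), evaluating the 5.8S/28S proximal-stem
    hybridization with nearest-neighbor thermodynamics, folding ITS2 spacers
    into minimum-free-energy secondary structures, classifying the four-helix
    fold into diagnostic structural models, and running sequence-structure
    phylogenetics (combined 12-letter alphabet alignment, K2P and log-det
    distances, neighbor-joining trees with bootstrap supports and pruning
    likelihoods) together with rank-based group statistics and barcode-gap
    evaluation. Includes a constructive synthetic-data generator so the whole
    pipeline is testable without any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    seqinr,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
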