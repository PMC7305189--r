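Package: coevopair
Title: Paired-Alignment Coevolution Analysis and Restraint Generation for
    Two-Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers residue-residue contacts for a two-protein complex from
    metagenome-derived sequence data. Gene hits from the same contig are
    paired by genomic adjacency into a concatenated alignment, which is
    redundancy-filtered, reweighted, and scored (effective sequence number,
    Nf). A pseudolikelihood Potts model with average-product correction
    yields ranked inter- and intra-chain contact predictions; these are
    assessed against structural contact maps (precision-at-k, interdomain
    sets, model-fit ratio Rc) and converted into folding-engine restraint
    files, including iron-sulfur cluster and corrinoid cofactor geometry
    derived from a reference ferredoxin. A synthetic-data module generates
    ground-truthed toy complexes, Potts-sampled sequence families, and
    metagenome contig sets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
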