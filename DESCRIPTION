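Package: itsmapr
Title: Atom-Atom Mapping of Chemical Reactions via Cyclic Transition State Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes chemically correct atom-atom maps for elementary chemical
    reactions. Reactions are given as kekulized SMILES; educts and products are
    represented as labeled multigraphs with explicit hydrogens and lone-pair
    bookkeeping. Candidate imaginary transition states (ITS) -- cyclic patterns
    of bond-order and lone-pair changes -- are enumerated with a finite-domain
    constraint solver (basic and extended formulations, including hydrogen
    symmetry breaking and neighborhood-multiset cardinality constraints), and
    each candidate is extended to complete atom maps by relabeling the ITS
    edges and enumerating label-preserving graph isomorphisms. Results are
    emitted as atom-mapped reaction SMILES.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
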