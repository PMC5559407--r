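Package: npenum
Title: Enumeration of Hypothetical Modular Natural Products and
    Benchmarking of Chemical Similarity Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@npenum.org",
           role = c("aut", "cre"))
Description: Combinatorial enumeration of hypothetical modular natural
    product structures (nonribosomal peptides, polyketides, and hybrids)
    from packaged monomer alphabets, controlled derivatization by monomer
    substitution and tailoring-reaction edits (macrocyclization,
    halogenation, O-glycosylation, thiazole/oxazole formation,
    N-methylation), and benchmarking of two-dimensional chemical
    fingerprints by their ability to match each derivative back to its
    parent structure within a library. Includes circular (ECFP/FCFP),
    substructure-key, topological path, and lexicographic (LINGO)
    fingerprints, Tanimoto ranking with strict tie semantics, and
    rank-based statistics (Brunner-Munzel tests, Kendall trend tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineOB,
    Rcpp,
    optparse,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
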