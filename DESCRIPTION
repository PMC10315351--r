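Package: fragcharge
Title: Fragment-Based Transfer of Partial Atomic Charges Between Molecules
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for parametrizing the partial atomic charges of a query
    molecule by re-using charges from a library of previously parametrized
    reference molecules. Atoms are considered equivalent only when their
    local chemical environments, defined by a bond-count shell size k, are
    isomorphic; all k-maximal common fragments between the query and each
    library molecule are enumerated, charges are transferred from selected
    fragments with explicit conflict resolution (select, average or manual),
    and the residual deviation from the target net charge is redistributed
    uniformly. Regions of the query not represented in the library are
    grouped with their chemical environment, split along acyclic bonds into
    pieces of manageable size without breaking rings, and capped with
    neutral hydrogens chosen by an exact combinatorial optimisation so they
    form chemically complete molecules ready for external parametrization.
    Includes built-in test molecules, a deterministic self-library generator
    and a brute-force enumeration oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, igraph, jsonlite, ChemmineR, ChemmineOB
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Cheminformatics, GraphAndNetwork, Software
RoxygenNote: 7.3.3
Collate:
    'fragcharge-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'molgraph.R'
    'io.R'
    'envmatch.R'
    'oracle.R'
    'charges.R'
    'missing.R'
    'fixtures.R'
    'pipeline.R'
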