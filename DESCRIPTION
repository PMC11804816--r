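Package: eccQSPR
Title: Eccentricity-Based Topological Indices and QSPR Regression for
    Molecular Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes eccentricity-based topological indices (total and
    average eccentricity, the three Zagreb eccentricity indices, the
    eccentric geometric-arithmetic index GA4, the eccentric
    atom-bond-connectivity index, and the eccentric harmonic index) on
    hydrogen-suppressed molecular graphs, and fits linear and quadratic
    quantitative structure-property relationship (QSPR) regressions of
    physicochemical drug properties on those indices, with F-test based
    significance screening. Molecular graphs are read from plain edge-list
    files or, optionally, from SMILES strings. Ships a curated dataset of
    thirteen anti-schizophrenia drugs (eight physicochemical properties and
    eight published index values each) together with the chlorpromazine
    heavy-atom skeleton, a degree-bounded random graph generator for
    property testing, and brute-force distance oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    ChemmineR,
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'molgraph.R'
    'indices.R'
    'qspr.R'
    'dataset.R'
    'synthetic.R'
    'pipeline.R'
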