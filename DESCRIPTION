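Package: netpharm
Title: Network Pharmacology Pipeline with MCODE Module Detection and
    Over-Representation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of the classical
    network-pharmacology workflow used to explain how multi-herb formulas act
    on disease: ADME screening of candidate compounds (oral bioavailability,
    Caco-2 permeability, drug-likeness), assembly of per-herb and union
    target gene sets, disease-gene relevance filtering, construction of a
    categorized protein-protein interaction network from STRING-dialect TSV
    exports, degree-based hub ranking, a from-scratch implementation of the
    MCODE molecular-complex detection algorithm (k-core vertex weighting,
    seed-and-grow, haircut and fluff post-processing, density-based cluster
    scoring), and hypergeometric/EASE over-representation analysis against
    GMT annotation collections with Benjamini-Hochberg correction and fold
    enrichment. A synthetic-data module generates every input dialect the
    pipeline consumes, with planted ground truth, so all stages are
    verifiable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
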