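Package: netpharm
Title: Network Pharmacology and Chemometric Evaluation of Multi-Herb Formulas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciphering active compounds and mechanisms of
    multi-herb formulas by network pharmacology, with a worked focus on the
    Qixuehe capsule and the qi-stagnation/blood-stasis syndrome. Implements
    Tanimoto-coefficient drug-likeness, the three-criterion ADMET gate with a
    biological-relevance whitelist, filtering of predicted compound-target
    interactions, tripartite herb-compound-target network construction with
    degree and betweenness centrality ranking, hypergeometric pathway
    over-representation with Benjamini-Hochberg control, cross-module overlap
    arithmetic, and pharmacodynamic evaluation by NIPALS PLS-DA with VIP
    scores, cross-validated Q2 and permutation validation. A seeded
    synthetic-data generator produces compound universes, annotation sets and
    rat cohorts with known planted structure so every stage is testable
    without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
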