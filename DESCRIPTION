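Package: hetnet
Title: Degree and Graph Heterogeneity Measures for Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A unified framework for quantifying degree and graph
    heterogeneity of undirected simple networks.  Implements three generic
    measure classes (dispersion aggregation, expected difference, and
    special measures), the battery of twelve named measures built from them
    (HN, HS, HF, HHG, HA, HE, HAp, HEp, HAED, HPED, HJ, HCS) together with
    normalized variants, seeded graph generators (Erdos-Renyi, power-law
    fitness, exponential-degree configuration, named families, completely
    diverse graphs), the three network manipulations used to probe measure
    behaviour (transfer rewiring, uniform degree addition, replication),
    a principle-compliance engine that assembles a per-measure verdict
    matrix with violation witnesses, and scaled random-graph sweep and
    extreme-topology experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
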