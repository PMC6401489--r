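Package: inhibnet
Title: Analysis of Multi-Condition Microbial Inhibition Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse pairwise antagonism (growth-inhibition) assays
    carried out across multiple growth conditions. Reads per-condition binary
    producer-by-receiver matrices, builds directed interaction networks with
    per-edge condition support, and computes community-level statistics:
    connectance, sender-receiver asymmetry, reward/penalty hierarchy scores,
    top-producer concentration, reciprocity, and cross-condition conservation
    (Venn partition of edges by the media in which they were detected).
    Includes degree-preserving permutation null models with empirical
    p-values, a synthetic-data generator based on a noisy-tournament latent
    hierarchy for validation, and exporters to SIF/GraphML for Cytoscape.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
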