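Package: amidenet
Title: Amide Scaffold Networks for Dual-Target Inhibitor Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven identification of shared amide pharmacophores for
    dual-target inhibitor design, demonstrated on the PARP1/BRD4 target pair.
    Curates target-annotated bioactivity tables into per-compound potency
    annotations (pPOT), decomposes compounds into ring systems by simultaneous
    cleavage of acyclic single bonds with an amide-preserving exception,
    classifies bicyclic and tricyclic amide scaffolds (primary amide on ring,
    or lactam), tallies scaffold support per target, organises scaffolds and
    targets into a bipartite network with crystallographic-evidence edge
    annotation, ranks shared scaffolds, profiles growth vectors, enumerates
    scaffold x substituent analogs in a SAR-matrix layout, and scores
    candidates with molecular weight, heavy atom count, Wildman-Crippen logP
    and ligand efficiency. Includes a synthetic bioactivity-data generator
    with planted scaffold structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
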