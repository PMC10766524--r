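Package: PocketPairNet
Title: Siamese Graph Attention Networks for Ranking Congeneric Ligand
    Binding Affinities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks the relative binding affinity (delta-pIC50) of
    congeneric ligand pairs docked into a shared protein pocket with a
    Siamese, physics-informed graph attention network.  Pocket-ligand
    complexes are encoded as directed molecular graphs with covalent,
    virtual distance and virtual aromatic edges; message passing
    alternates between distance/angle-aware edge-to-edge and
    distance-aware edge-to-node attention blocks, with a knowledge-based
    atom-pair statistical potential as an additive attention bias.  The
    package also provides the pairwise data pipeline (activity cleaning,
    pair enumeration, similarity filtering, label balancing),
    reference-anchored inference with uncertainty, hybrid-loss training
    and few-shot fine-tuning, an active-learning campaign simulator for
    lead optimization, attention and substructure-mask interpretability,
    and a synthetic congeneric-series generator so the whole system can
    be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    bio3d,
    ChemmineR,
    ChemmineOB,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
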