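Package: allostate
Title: Markov State Models, Feature-Importance Communities, and Transition
    Path Analysis for Protein Allostery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated workflow for dissecting allosteric conformational
    change in protein molecular-dynamics ensembles. Trajectories are
    featurized as pairwise C-alpha distances and two-dimensional RMSD
    collective variables, discretized into microstates by k-means, and
    coarse-grained into metastable macrostates through a reversible
    maximum-likelihood Markov state model with Perron-cluster lumping and
    Chapman-Kolmogorov validation. One-vs-one random-forest classifiers
    quantify the per-feature distinguishability of macrostate pairs, and a
    Kernighan-Lin style multi-restart search partitions residues into
    communities that minimize intra-community feature importance, so that
    inter-community geometry carries the state-discriminating signal.
    Transition path theory on the macrostate model yields committors,
    reactive fluxes, and pathway/channel decompositions. A seeded synthetic
    trajectory generator with planted metastable states and planted
    communities supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    rpart,
    nnet,
    igraph,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
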