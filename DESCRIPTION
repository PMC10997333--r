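Package: incstruct
Title: Incremental Structural Interpretation of Spoken Sentences with
    Structural Probing and Spatiotemporal Searchlight RSA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how sentence structure is interpreted
    incrementally during speech comprehension. Implements linear structural
    probing of contextual word embeddings to dependency parse depths,
    corpus-ratio constraint indices (agenthood/patienthood,
    transitivity/intransitivity, passive/active and non-directional
    interpretative-coherence indices), interpretation geometry in parse-depth
    model space (landmarks, trajectories, interpretative mismatch),
    spatiotemporal searchlight representational similarity analysis with
    multivariate noise normalization and cluster-based sign-flip permutation
    inference, and non-negative matrix factorization of model-fit maps
    followed by multivariate Granger causality with surrogate-based
    significance. A synthetic-data module generates every input the pipeline
    consumes (dependency trees, embeddings, corpus count tables, continuation
    tables, cortical meshes, source-space epochs with planted
    representational geometry), so the full analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
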