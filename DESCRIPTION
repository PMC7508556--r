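Package: morphotraj
Title: Phenotypic Trajectory Analysis of the Anolis Locomotor Skeleton
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-morphometric inference for repeated (parallel) evolution
    of island ecomorphs. Turns 3D landmark configurations and linear bone
    measurements into a scaled multivariate trait space (generalized Procrustes
    superimposition, size correction, standard-normal-deviate scaling), computes
    t-value phenotypic trajectory vectors between ecomorph groups, tests
    parallelism of divergence across islands via vector angles and length
    differences with permutation and bootstrap significance, quantifies
    phylogenetic convergence with a Wheatsheaf-style index, ranks traits by
    outlier scores, and assigns sex from pelvic shape with a posterior-threshold
    linear discriminant. A synthetic-data generator with recorded ground truth
    emulates an island radiation plus a two-species rearing experiment so that
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    stats,
    utils
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
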