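Package: CrossRankNoN
Title: Disease Gene Prioritization on Networks of Tissue-Specific Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models a disease similarity network whose nodes each carry one
    or more tissue-specific molecular networks (a network of networks, NoN,
    or a network of star networks, NoSN) and prioritizes candidate disease
    genes on these models by graph-regularized label propagation. Implements
    the CrossRank, CrossRankStar and weighted CrossRankStar objectives with
    convergent fixed-point solvers and a direct sparse linear-system oracle,
    simplex-constrained learning of auxiliary-network weights, construction
    of tissue-specific co-expression networks (WGCNA soft thresholding plus
    k-nearest-neighbor sparsification), disease-tissue network assignment,
    leave-one-out and temporal-split evaluation with truncated ROC areas,
    and a synthetic network-of-networks generator with planted disease
    modules for fully reproducible benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
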