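Package: dpsynth
Title: Differentially Private Synthetic Clinical Cohorts via Auxiliary-Classifier GANs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generates shareable synthetic longitudinal clinical cohorts with
    formal (epsilon, delta) differential-privacy guarantees. Trains an
    auxiliary-classifier generative adversarial network (AC-GAN) on
    participant-by-visit matrices such as blood-pressure trial records, with
    the discriminator updated by differentially private stochastic gradient
    descent (per-participant gradient clipping plus Gaussian noise under
    Poisson lot subsampling). A moments accountant tracks the exact privacy
    spend, generator checkpoints are selected privately with the exponential
    mechanism, and a utility-evaluation suite compares real and synthetic
    cohorts by correlation structure, summary statistics, treatment-decision
    rates, and train-on-synthetic/test-on-real classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    randomForest,
    e1071,
    class,
    pROC
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StatisticalMethod, Software, Classification
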