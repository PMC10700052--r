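Package: effsel
Title: Effective Fitness and Selection-Drift Decomposition Under
    Fluctuating Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation of a haploid Wright-Fisher population under
    temporally fluctuating selection, with an exact per-generation
    decomposition of allele-frequency change into a selection component and
    a binomial drift residual. Provides the geometric mean fitness, the
    effective fitness (the constant fitness that would produce the observed
    mean selection-driven frequency change at frequency one half), and the
    relative selection effect C used to call effective neutrality. Includes
    exact binomial-expectation computations showing that geometric mean
    fitness is a biased summary of fluctuating selection in the presence of
    drift, and batch experiment drivers for frequency prediction,
    fixation/loss classification (ROC/AUC), and new-mutation fate analysis.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
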