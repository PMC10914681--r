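Package: viewchoice
Title: View-Based Decision Circuits and Amygdala-Style Population Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying view-based economic choice with sequentially
    presented options. Provides a synthetic-session generator (block-wise
    reward probabilities, trial-wise cued magnitudes, reinforcement-learning
    agents, Poisson spike counts for functional amygdala cell types, eye
    traces), a family of reinforcement-learning models with maximum-likelihood
    fitting and AIC/BIC comparison, a session-level logistic value model and
    an optimality grid, a three-stage firing-rate circuit model (integral
    feedback value comparison, winner-take-all view-based decision, expansion
    recoding to object choice) with bifurcation analysis, ablation variants
    and a many-objects extension, and the matching population analyses:
    single-neuron GLMs with angle-based value classification and
    permutation-calibrated sliding-window regression, pseudo-population
    decoding with cross-condition generalization and label recoding, and
    representational similarity analysis with template regression and
    permutation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    e1071,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
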