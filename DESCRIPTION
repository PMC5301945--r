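Package: aziflow
Title: Kinetic Modelling, Model-Based Design of Experiments and
    Self-Optimisation for a C-H Activation Flow Process
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic kinetic modelling of the palladium-catalysed
    C(sp3)-H activation of an aliphatic amine to an aziridine in segmented
    flow, together with the model-development and self-optimisation
    machinery built around it: a stiff batch-segment simulator of the
    reaction network, a noisy virtual laboratory emulating GC-sampled flow
    experiments, local dynamic sensitivity and estimability analysis,
    D-optimal model-based design of experiments with predicted t-tests,
    staged weighted least-squares parameter estimation with confidence
    intervals, process objectives (yield, product output, energy and
    specific cost), and a multi-objective active-learning target optimiser
    combining Gaussian-process surrogates, binary Gaussian-process
    feasibility classification and NSGA-II refinement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
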