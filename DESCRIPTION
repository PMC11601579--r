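Package: sahnet
Title: Sample-and-Hold Recurrent Networks with Common-Mode Inputs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, training, reduction and analysis of sign-constrained
    dynamic recurrent neural networks performing a sample-and-hold short-term
    memory task on two continuous inputs that share a parametric common-mode
    component. Provides the seeded task generator, a logistic-unit network
    model obeying Dale's principle, backpropagation-through-time training with
    line search, a staged weight-decay and unit-deletion reduction schedule,
    and analysis tools for cross-common-mode generalization, input lesions and
    fixed-point attractor maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
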