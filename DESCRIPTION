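Package: pmdtune
Title: Neural Tuning and Population Decoding for Premotor Reach-and-Grasp Ensembles
Version: 0.1.0
Authors@R:
    person("pmdtune", "developers", email = "pmdtune@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of dorsal premotor (PMd) spike-train
    recordings from separated reaching and grasping paradigms. Provides an
    inhomogeneous-Poisson session simulator with planted tuning categories,
    spike alignment and binning utilities, one-way ANOVA tests for
    task-related and direction/object-tuned activity, plug-in mutual
    information between 10-ms spike indicators and action labels with a
    cumulative-information threshold rule for classifying neurons as tuned
    to reaching only, grasping only, both, or neither, and multiclass
    radial-basis-function support-vector-machine decoding experiments that
    quantify each neuron subset's contribution to action classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
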