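Package: attractorFano
Type: Package
Title: Stimulus-Driven Spike-Count Variability Reduction in Multistable
    Attractor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conductance-based integrate-and-fire simulation of a fully
    connected, clustered cortical network with AMPA, NMDA and GABA-A
    synapses; mean-field fixed-point and bifurcation analysis of its
    multistable attractor landscape; and trial-based spike-train statistics
    (origin-constrained Fano-factor regression, mean matching, ISI CV and
    CV2, Gaussian-kernel rate estimation). Includes doubly stochastic
    surrogate generators (Poisson, gamma renewal, Markov-modulated Poisson)
    with a closed-form MMPP count Fano factor, and experiment protocols that
    quantify how external stimulation and attentional bias reduce
    across-trial spike-count variability by stabilising one attractor of a
    multistable set.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    pracma,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
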