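Package: plastnet
Title: Simulation of Spike-Driven Synaptic Plasticity from Single Synapses to Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained simulator for spike-driven synaptic plasticity in
    neurons and recurrent networks. Provides counter-based (Threefry-4x64)
    pseudorandom number streams and Euler-Maruyama integration of stochastic
    differential equations; branched neuronal morphologies with implicit
    (backward-Euler, Hines-ordered) solvers for the cable equation and for
    particle diffusion along dendrites; leaky integrate-and-fire and
    Hodgkin-Huxley point dynamics with delayed event delivery and a
    postsynaptic-spike dispatch hook; five plasticity rules (pair-based STDP,
    spike-driven homeostasis, calcium-based bistable plasticity,
    heterosynaptic calcium-diffusion plasticity on dendritic spines, and
    two-phase synaptic tagging-and-capture with plasticity-related protein
    synthesis); and recurrent-network experiments measuring memory recall by a
    pattern-completion coefficient, including morphological-cell variants with
    intracellular signal diffusion and a spike-propagating ring benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
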