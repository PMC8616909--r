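Package: netmfa
Title: Node-Based Multifractal Analysis of Complex Networks
Version: 0.1.0
Authors@R:
    person("netmfa", "developers", email = "netmfa@example.org", role = c("aut", "cre"))
Description: Node-based fractal dimension (NFD) and node-based multifractal
    analysis (NMFA) for undirected, optionally edge-weighted networks.
    Implements the box-growing method (per-node cumulative mass profiles over
    growing shortest-path radii), partition functions, mass exponents,
    Legendre multifractal spectra and generalized dimensions, together with
    derived comparative metrics: a structure distance between generalized
    dimension curves, a spectrum asymmetry index, a thermodynamics-inspired
    specific heat with phase-transition (peak) detection, and an
    edge-deletion robustness experiment. Ships reference generators (ring
    lattice, Erdos-Renyi, Watts-Strogatz, Barabasi-Albert, weighted
    self-similar fractal trees, (u,v)-flowers) used for validation, plus a
    small command-line pipeline for batch analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
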