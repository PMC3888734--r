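Package: causticfold
Title: Stationary-Action Analysis of Torsion-Angle Chain Dynamics
Version: 0.1.0
Authors@R:
    person("Causticfold", "Developers", email = "causticfold@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the stability of folding-like motions of
    chains of dihedral angles with Lagrangian mechanics. Integrates the
    Euler-Lagrange equations for configurable torsional potentials
    (harmonic, asymmetric angular springs, quartic cusp), evaluates the
    action and its first and second variations along trajectories, locates
    conjugate points by both an eigenvalue scan of the discretized second
    variation and Jacobi-field integration, detects caustics and foci of
    trajectory families from the family action surface, classifies local
    actions against the seven elementary catastrophe normal forms with
    perturbation-stability testing, computes Boltzmann moment statistics of
    catastrophe potentials, and provides transition-state-theory folding
    rates with denaturant chevron curves and a contact-order scaling hook.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
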