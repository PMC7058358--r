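Package: crnlyap
Title: Robust Lyapunov Functions for Chemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetics-independent stability analysis of chemical reaction
    networks. Given only the stoichiometry and reactant pattern of a network,
    constructs Robust Lyapunov Functions (RLFs) that certify a unique, globally
    stable steady state under every admissible monotone kinetics: piecewise
    linear-in-rates certificates by linear programming, by an iterative
    row-growing algorithm, and by a graphical Max-Min criterion, plus a
    piecewise quadratic-in-rates semidefinite relaxation. Networks are screened
    against necessary conditions (the P0 property of the negative Jacobian,
    absence of critical siphons, robust non-degeneracy), and every certificate
    can be validated numerically against simulated mass-action,
    Michaelis-Menten, and Hill kinetics. Includes a catalog of signalling
    motifs (post-translational modification cycles and cascades,
    phosphorelays, kinetic proofreading, ERK/RKIP, the ribosome flow model)
    and quantitative tools built on the certificates: safety level sets and
    dynamic flux bounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    MASS,
    minpack.lm,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
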