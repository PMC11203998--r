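Package: funnelmetad
Title: Funnel Metadynamics on Toy Ligand-Binding Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Langevin sampling with well-tempered, multiple-walker metadynamics
    inside a cone-plus-cylinder funnel restraint, modelled on the protocol used
    for peptide-integrin binding free energies. Provides the two collective
    variables of that protocol (funnel-axis centre-of-mass projection and a
    contact-map distance built from rational switching functions), hill
    deposition and replay, steered moving restraints, free-energy surfaces from
    the bias and by reweighting, bound-frame extraction, heavy-atom contact and
    water-mediation analyses, Kabsch superposition, and PLUMED-dialect
    COLVAR/HILLS text I/O. Synthetic systems with quadrature-known free
    energies make every stage testable without external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr
Config/testthat/edition: 3
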