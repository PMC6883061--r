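Package: fibnp
Title: Nanoparticle-Amyloid Fibril Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure generators and trajectory analytics for studying how
    ligand-coated gold nanoparticles couple to amyloid-beta (Abeta40) fibrils.
    Builds idealized two-protofilament cross-beta fibrils with a controllable
    per-peptide axial twist, ligated icosahedral-core nanoparticle models
    (positive, negative, inhibitor-carrying, Janus and peptide-coated shells),
    and synthetic multi-frame trajectories. Analyses include the inter-peptide
    twist-angle statistic, Monte-Carlo (Shrake-Rupley style) solvent-accessible
    surface areas and SASA-difference contact areas, heavy-atom contact
    counting, and screened Coulomb plus Lennard-Jones (12,6) interaction-energy
    decomposition with per-residue attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
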