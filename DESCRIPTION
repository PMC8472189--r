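Package: pcbtrans
Title: Transformation Products and Environmental Risk Characterization of
    Polychlorinated Biphenyls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based enumeration of polychlorinated biphenyl (PCB)
    transformation products along four environmental pathways (plant
    degradation to chlorobenzoic acids, microbial aerobic hydroxylation,
    microbial anaerobic reductive dechlorination, biometabolism to
    methylsulfonyl metabolites, and photodechlorination), built on a
    first-principles derivation of the 209-congener numbering. Includes a
    comparative molecular field analysis (CoMFA-style) 3D-QSAR engine with
    grid-based steric and electrostatic fields, NIPALS partial least squares
    with leave-one-out q2 model selection, a five-endpoint environmental
    risk change-rate analysis (phytotoxicity, estrogen toxicity,
    bioconcentration, persistence, migration), and the validation
    arithmetic for comparing docking-derived activities with model
    estimates. The study's printed data tables ship as machine-readable
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
SystemRequirements: Open Babel (obabel) for 3D conformer generation
Config/testthat/edition: 3
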