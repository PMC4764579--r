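Package: toxinterface
Title: Contact, Density-Fit and Membrane-Partitioning Analytics for
    Toxin-Channel Structural Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analytics for studies of peptide toxins bound to
    membrane ion channels: contacting-atom-pair (Np) statistics on
    multi-model coordinate ensembles, including residue-residue contact
    maps, lipid head/tail contact profiles and hydrophobic-cluster
    compactness; cryo-EM density-map model scoring (map-model correlation,
    per-atom mass-weighted density confidence) and NOE restraint-violation
    pose ranking; ensemble geometry (Kabsch superposition, RMSD to the
    iterated mean, Daura clustering, Shrake-Rupley solvent-accessible
    surface area, buried interface area); and the thermodynamics of
    membrane partitioning and channel dose-response (mole-fraction
    partition coefficient fits, Hill fits, free-energy additivity of
    bivalent toxins). A synthetic-data module generates toy complexes,
    lipid slabs, Gaussian-atom density maps and noisy titrations so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
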