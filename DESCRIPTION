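Package: csens
Title: Conformational Sensitivity of Predicted Protein NMR Chemical Shifts
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to test whether predicted NMR chemical shifts can
    distinguish distinct microscopic conformations of a disordered peptide.
    Provides multi-model PDB input, radius-of-gyration frame selection and
    Kabsch superposition, per-residue QM cluster fragmentation with ACE/NME
    capping and first-shell micro-solvation, conversion of isotropic
    shieldings to chemical shifts by TMS and methylamine secondary-standard
    referencing, a per-atom two-group conformational-sensitivity statistic in
    multiples of the pooled standard deviation with Gaussian-overlap
    thresholding, validation against experimental shifts (mean relative
    error) and random-coil baselines (secondary chemical shifts), a
    random-forest permutation feature-importance study of per-atom
    biophysical features, and a fully seeded synthetic-data generator that
    emulates two conformation groups of five near-identical configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
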