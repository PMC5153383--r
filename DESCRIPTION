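Package: ablate90
Title: Voxel Dosimetry and Simulated Adjuvant Thermal Ablation for
    Yttrium-90 Radioembolization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative yttrium-90 voxel dosimetry after
    radioembolization and for biophysical simulation of adjuvant
    radiofrequency ablation of under-dosed tumor regions.  Implements
    local-deposition-method dose maps, dose-volume histograms and Dxx/V100
    metrics on voxel grids; a Pennes bioheat finite-difference solver with
    Joule heating from a quasi-static potential solution, a 105 degree
    Celsius feedback controller, and Arrhenius models of cell death and
    vascular coagulation; electrode-plan validation against organ-at-risk
    constraints; a per-tumor pipeline that subtracts predicted ablation
    zones from tumor masks and recomputes dose metrics; cohort-level
    statistics; and a synthetic phantom generator emulating heterogeneous
    post-radioembolization activity distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    nortest,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
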