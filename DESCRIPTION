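Package: dirdose
Title: Deformable-Registration Dose Accumulation for Combined External-Beam
    Radiotherapy and Brachytherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise dose accumulation for cervical-cancer radiotherapy
    courses that combine whole-pelvis and center-shielded external-beam plans
    with high-dose-rate intracavitary brachytherapy. Provides a synthetic
    pelvic phantom generator with analytically controlled ground-truth
    deformations, rigid and deformable image registration (intensity-based and
    hybrid intensity-plus-structure modes), EQD2 conversion under the
    linear-quadratic model, dose warping and summation on a reference frame,
    and hottest-subvolume dose-volume-histogram metrics (D 0.1/1/2 cm3, D90),
    together with the GEC-ESTRO-style DVH parameter addition baseline and
    tidy report/plot methods for comparing the two accumulation strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
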