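Package: motoret
Title: Subtomogram Averaging and Geometry of the Spirochetal Flagellar Motor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale cryo-electron tomography analysis of bacterial
    flagellar motors: synthetic motor phantoms with strain-specific C-ring
    tilt and stator occupancy, missing-wedge simulation, wedge-aware
    constrained cross-correlation alignment, Fourier-space subtomogram
    averaging with per-voxel coverage normalization, half-set Fourier shell
    correlation, rotational-symmetry detection by angular harmonic analysis,
    focused stator-site classification with an occupancy statistic, and
    C-ring tilt measurement by ellipse fitting of axial cross-sections.
    Volumes are read and written as MRC2014; particle metadata as TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
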