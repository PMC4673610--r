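Package: clemalign
Title: Fiducial-Based Registration of Correlative Light and Scanning
    Electron Microscopy Images
Version: 0.1.0
Authors@R:
    person("CLEM", "Tools", email = "maintainer@clemalign.org", role = c("aut", "cre"))
Description: Registration toolbox for correlative light-electron microscopy
    (CLEM) experiments that use stochastic gold micro-patterns as fiducial
    markers. Segments gold micro-islands from bright-field and back-scatter
    electron images, stitches bright-field tiles into a whole-coverslip
    global map by phase correlation, locates a region of interest on the map
    under unknown similarity transform with a scale- and rotation-invariant
    keypoint detector, estimates rotation and translation between light and
    electron micrographs by an exhaustive rotation sweep, fuses fluorescence
    channels into electron-microscope coordinates, and ships a synthetic
    random-dot benchmark that measures alignment efficiency and sub-pixel
    accuracy of the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
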