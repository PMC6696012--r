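Package: ms3d
Title: Multispectral 3D Point-Cloud Measurement of Plant Canopies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build multispectral 3D point-cloud models of potted
    plants imaged on a turntable by an RGB-D camera and a co-mounted
    narrow-band reflectance imager. Registers reflectance bands into the
    depth camera's pixel grid with Fourier phase correlation and the
    Fourier-Mellin log-polar method, self-calibrates the turntable
    rotation axis from colored calibration stickers, fuses multiview
    depth frames into a single canopy cloud by closed-form rough
    alignment followed by iterative closest point refinement, and
    computes per-point vegetation indices and SPAD chlorophyll
    calibration models from the fused cloud. Includes a synthetic
    turntable-scene generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    minpack.lm,
    png,
    tiff,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
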