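Package: grassRNet
Title: Spectral-Spatial 3D Residual Networks for UAV Hyperspectral
    Grassland Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classification of grassland-degradation indicator vegetation
    (group species, degradation indicator species, and non-vegetation) from
    UAV hyperspectral reflectance cubes. Provides ENVI cube input/output and
    scene assembly, PCA band reduction with 3D patch extraction, a family of
    residual classification networks including a dual-branch spectral/spatial
    3D residual network with exact parameter accounting, a compact CPU
    training engine, remote-sensing accuracy assessment (overall, average and
    per-class producer's/user's accuracy with the kappa coefficient),
    classification-map rendering, and a synthetic hyperspectral scene
    simulator with patchy communities, drought-flattened spectra and mixed
    border pixels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
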