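Package: octads
Title: De-Shadowing of Tail Artifacts in OCT Angiography Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Suppression of multiple-scattering tail artifacts ("shadows")
    beneath large superficial vessels in volumetric optical coherence
    tomography angiography (OCTA) data. Implements per-A-line
    mean-subtraction de-shadowing with a tunable weight, the classical
    step-down exponential filtering baseline with attenuation-matched
    parameter selection, slab extraction and en face angiogram generation
    by maximum amplitude projection, quantitative evaluation metrics (RMS
    line contrast, capillary signal-to-noise ratio, adjacent-slab
    cross-correlation similarity), and a seeded synthetic
    cerebral-vasculature phantom generator with ground-truth artifact
    masks. Volumes are read and written as multi-page TIFF stacks or raw
    binary with JSON sidecar metadata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
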