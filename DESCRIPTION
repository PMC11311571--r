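Package: oralmark
Title: Quantitative OCT Biomarkers of Oral Mucosa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-A-line morphologic, attenuation, and stratification
    biomarkers from segmented endoscopic optical coherence tomography (OCT)
    volumes of oral mucosa: epithelial depth, loss of the epithelial-stromal
    boundary, depth-resolved attenuation coefficients (overall, epithelium,
    stroma), and ratiometric stratification features, reduced to per-volume
    medians and compared with a normality-routed statistical protocol.
    Includes readers and writers for multi-page TIFF volumes with JSON
    metadata sidecars, isotropic bicubic rescaling, en face projection, and a
    seeded two-layer speckle phantom generator with ground-truth surfaces and
    masks so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    jsonlite,
    yaml,
    car,
    ggplot2,
    rlang,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
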