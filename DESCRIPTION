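Package: retinaglare
Title: Retinal Contrast Simulation of Intraocular Veiling Glare
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts calibrated display stimuli into the pattern of light on
    the retina by convolving scene luminance with the CIE age- and
    pigmentation-parameterized glare spread function, and quantifies how
    intraocular veiling glare redistributes light in lightness-illusion
    stimuli. Includes generators for simultaneous-contrast and assimilation
    targets (striped White's-style panels, Todorovic circles and crosses, a
    black-and-white Mondrian under an illumination gradient), display
    calibration from photometer tables, log-luminance range mapping,
    pseudocolor look-up-table visualization, and region-of-interest analyses
    of glare's paradoxical light redistribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    tiff,
    tools,
    stats,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: fftw3
Config/testthat/edition: 3
RoxygenNote: 7.3.3
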