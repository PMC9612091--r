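Package: sfdimap
Title: Spatial Frequency Domain Imaging of Tissue Water and Lipid Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for quantitative mapping of tissue water and lipid
    content with spatial frequency domain imaging (SFDI) in the 900-1000 nm
    wavelength region. Demodulates three-phase structured-light image stacks,
    calibrates them to diffuse reflectance against a reference phantom,
    inverts reflectance at a pair of spatial frequencies to absorption and
    reduced scattering maps through a lookup table built from a
    diffusion-approximation forward model, and unmixes chromophore
    concentrations (water, lipid, oxy- and deoxyhemoglobin) by Beer's-law
    least squares. Includes Cramer-Rao-bound analysis for spatial-frequency
    selection, a wavelength-increment simulation study, a synthetic
    acquisition renderer for end-to-end validation, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
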