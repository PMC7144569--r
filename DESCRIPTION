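Package: serumAF
Title: Spectral Unmixing of Serum Autofluorescence into Endogenous Fluorophore Components
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decomposes serum autofluorescence emission spectra into
    endogenous-fluorophore components (retinol, arachidonic, linoleic and
    oleic acids, serum proteins, and auxiliary bands) using half-Gaussian
    modified Gaussian (GMG) band models fitted by bounded
    Levenberg-Marquardt least squares. Provides the two-stage
    control-then-treated fitting protocol, percentage and area-corrected
    absolute contribution estimates, the arachidonic-acid to retinol
    balance index, group summary statistics, and a synthetic serum-spectrum
    generator that emulates sham versus ischemia/reperfusion cohorts for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
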