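Package: SeagrassDyn
Title: Shallow-Water Seagrass Meadow Mapping and Change Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping seagrass meadows from shallow-water
    multispectral imagery and for quantifying their dynamics between two
    epochs. Implements water-column correction of surface reflectance via
    an analytical optically-shallow-water model (deep-water reflectance
    estimation, diffuse attenuation coefficients from a depth regression
    over a sandy calibration zone, inversion to bottom reflectance),
    two-class supervised benthic classification (Gaussian maximum
    likelihood, support vector machine, bagged random trees),
    confusion-matrix accuracy assessment with Cohen's kappa, and
    stable/loss/gain categorical change analysis with hectare area
    summaries. Includes a synthetic coastal-scene generator so the full
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, jsonlite, tools, utils
Suggests: testthat (>= 3.0.0), MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
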