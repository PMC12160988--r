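Package: pallorkit
Title: Quantification of Optic Disc Pallor from Color Fundus Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures optic disc pallor in color fundus photographs as
    vessel-excluded red/green reflectance ratios of the neuro-retinal rim,
    sectored into the standard peripapillary zones (temporal, nasal, their
    superior/inferior obliques and the papillomacular bundle) relative to a
    peripapillary control region. Includes a synthetic fundus-image generator
    with full ground truth, automated image quality-control proxies, a
    synthetic matched case-control cohort generator with known effect sizes,
    and the matched-cohort statistical arm (age/sex matching, standardization,
    adjusted logistic and linear models, sensitivity analyses) used to study
    disc pallor in Parkinson's disease.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    MASS,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
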