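Package: iolpost
Title: Intraocular Lens Power Calculation After Myopic Corneal Refractive
    Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Haigis thin-lens vergence optics for intraocular lens (IOL)
    power calculation in eyes with prior myopic corneal refractive surgery.
    Provides effective lens position prediction, IOL power selection for a
    target refraction, predicted refraction for an implanted lens, and
    closed-form back-calculation of the corneal power ("refraction-derived
    K", Krd) that explains an observed postoperative refraction. Ships the
    published regression corrections for Scheimpflug total corneal
    refractive power (TCRP) and total refractive power (TRP) 4.0 mm zone
    keratometry, re-derives such calibrations from any cohort by ordinary
    least squares, computes refractive prediction-error summaries
    (mean/median absolute error, percentage of eyes within 0.5 D and
    1.0 D), and runs the paired statistical comparisons used to benchmark
    IOL formulas. A seeded synthetic post-LASIK cohort generator makes the
    whole chain testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
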