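Package: mixref
Title: Indirect Reference Intervals from Mixed Laboratory Data by
    Maximum-Likelihood Mixture Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Establishes clinical reference intervals from mixed real-world
    laboratory records by the indirect (maximum-likelihood) method: a
    record-cleaning cascade with a full audit trail, kernel-density
    initialised expectation-maximisation fitting of a parametric healthy
    component (gamma or normal) plus pathologic contamination components,
    Kolmogorov-Smirnov main-part diagnostics and model selection, and
    parametric 2.5/97.5 percentile reference limits.  Includes a
    trimester-stratified thyroid-hormone (TSH, FT4) application with
    guideline comparison statistics, and a synthetic-cohort generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
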