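Package: cohensdCS
Title: Spatial Confidence Sets for Cohen's d Effect-Size Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs simultaneous spatial confidence sets (CSs) for the
    excursion set of a Cohen's d effect-size image estimated from a one-sample
    design: given N aligned subject-level maps, an effect-size threshold c and
    a confidence level 1-alpha, produces nested upper and lower set maps that
    bracket the true set {d(s) >= c} with simultaneous coverage. Critical
    values are obtained by a wild t-bootstrap of the supremum of a studentized
    residual field over the sub-voxel interpolated, noncentral-t bias-corrected
    plug-in boundary. Three constructions are provided: a limiting-variance
    standardization, a sample standard-deviation standardization, and an
    arcsinh variance-stabilizing transformation that also removes the skew of
    the Cohen's d estimator in small samples. Includes a synthetic signal and
    smoothed Gaussian noise generator and a Monte-Carlo harness for coverage
    and sensitivity experiments, plus NIfTI input/output and a command-line
    interface for real imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    RNifti,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
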