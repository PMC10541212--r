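Package: rsi3c
Title: Automated Breast Tumor Response Assessment from Multi-b-Value
    Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a three-component fixed-diffusivity signal model to
    multi-b-value diffusion-weighted MRI, converts the restricted and
    hindered signal contributions into voxel-wise posterior probabilities
    of cancer via a pooled joint-density lookup table, automatically
    measures the longest tumor diameter inside a dilated tumor-containing
    region across longitudinal time points, and evaluates treatment
    response against a binary pathology endpoint with ROC, exact binomial,
    McNemar and DeLong statistics. Includes a synthetic digital phantom
    generator (Rician noise, longitudinal tumor shrinkage) so the whole
    pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
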