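Package: persdecon
Title: Personalized Cell-Type Deconvolution for Repeated-Measures Bulk Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-stage personalized cell-type deconvolution for longitudinal or
    otherwise repeatedly measured bulk RNA-seq. Stage one estimates coarse cell-type
    proportions for every sample against a population-level signature matrix with linear
    nu-support-vector regression; stage two fits per-gene linear mixed-effect models with
    subject-level random slopes on the proportions to recover subject- and cell-type-specific
    reference panels; stage three re-deconvolutes each subject's samples against their
    personalized panel by non-negative least squares (or sample-wise nu-SVR). Also provides
    a Gamma-Dirichlet-Poisson simulator of longitudinal bulk counts with full ground truth,
    and compositional evaluation metrics (absolute bias difference, correlation difference,
    Lin's concordance correlation coefficient and Euclidean/Aitchison variants).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    lme4,
    pracma,
    MASS,
    Matrix,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
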