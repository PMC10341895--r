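Package: deconvmix
Title: First-Generation Cell Mixture Deconvolution Methods with a
    Ground-Truthed Benchmarking Layer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cell-type proportions from bulk transcriptomic
    mixtures under the linear mixing model B = S * P. Implements the
    classic first-generation deconvolution estimators in one interface:
    non-negative least squares, nu-support-vector regression
    (CIBERSORT-style), Huber robust linear regression with optional
    per-cell-type mRNA-abundance scaling (ABIS-style), adaptive least
    trimmed squares with iterative outlier removal (FARDEEP-style),
    fixed-point independent component analysis (DECONICA-style), and
    simplex-corner identification with mutual-linearity marker discovery
    (LINSEED-style). Ships a marker-block mixture simulator with known
    ground truth, an evaluation layer (real-versus-estimated correlation
    matrices, per-cell-type root mean square error, bar-mixture and
    cell-signature tables), marker-signature refinement against a
    reference signature matrix, and a deterministic multi-method
    comparison pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    e1071,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
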