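Package: assd
Title: Adaptive Shortest-Solution Guided Decimation for Sparse
    High-Dimensional Linear Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits sparse high-dimensional linear regression models
    (p > n) by adaptive shortest-solution guided decimation (ASSD):
    greedy support construction guided by the minimum l2-norm
    least-squares solution of the recursively decimated linear system,
    with an early-stopping rule on the residual norm and the step count,
    followed by BIC-guided hard thresholding of the selected
    coefficients. Includes the plain decimation variants (naive residual
    stopping, and early stopping without refinement) for ablation,
    generators for correlated Gaussian and low-rank structured
    measurement matrices, a replicated simulation harness with
    true/false-positive and relative-error metrics, and delimited-text
    input/output with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
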