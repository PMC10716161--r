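Package: imri
Title: Real-Time Interventional MRI Reconstruction with Low-Rank, Sparse
    and Framelet Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-wise reconstruction of golden-angle radial k-space for
    real-time interventional MRI. Implements the LSFP variational model (a
    low-rank plus sparse decomposition of the image sequence with framelet
    and temporal total-variation penalties) solved by a primal-dual
    fixed-point algorithm, an unrolled-network variant with learned
    sparsifying transforms trained by Adam, a multi-coil non-uniform
    Fourier encoding operator with Kaiser-Bessel gridding, a synthetic
    brain-intervention simulator, and evaluation tools (PSNR, SSIM,
    needle-tip depth tracking).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    rhdf5,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
LinkingTo: Rcpp
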