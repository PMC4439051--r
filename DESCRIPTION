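Package: ccspat
Title: Case-Control Spatial Point Pattern Analysis for Disease Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the two standard spatial inference procedures on
    geocoded case-control point data: the Diggle-Chetwynd difference of K
    functions D(s) with random-labeling Monte Carlo envelopes for overall
    spatial clustering, and the Kulldorff Bernoulli spatial scan statistic
    with Monte Carlo p-values for cluster detection. Includes Ripley's
    isotropic edge-corrected K-function estimation over polygonal study
    windows, a synthetic generator for matched case-control datasets
    (inhomogeneous population intensity, stratum-matched controls, optional
    injected excess-risk clusters, privacy jitter of coordinates), and a
    per-cause, per-region study pipeline with CSV/GeoJSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
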