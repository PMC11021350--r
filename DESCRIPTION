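Package: statrace
Title: State-Trace Analysis by Conjoint Monotonic Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests whether two dependent variables measured across a common
    set of experimental conditions are consistent with a single latent
    dimension. Fits conjoint monotonic regression (weighted isotonic fits of
    both variables under a common total order of conditions, found by
    exhaustive, branch-and-bound or multistart search) and tests the
    one-dimensional null with participant-resampling or parametric-normal
    bootstrap. Includes a scoring pipeline from item-level yes/no/don't-know
    social-inference responses (think/do/feel probes, target/lure items,
    emotion-perception median split) to endorsement-rate state-trace
    datasets, and a synthetic generator with known latent dimensionality for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
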