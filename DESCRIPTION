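Package: cpgflex
Title: Predicted Gene Body Methylation from CpG Depletion and Its Link
    to Expression Flexibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for predicting gene body DNA methylation from
    transcript sequences via the length-corrected CpG observed/expected
    ratio, classifying genes into low- and high-CpG components with a
    two-component Gaussian mixture (EM) split at the component-density
    intersection, testing GO-slim biological-process enrichment of the
    components with Fisher's exact test, calling differential expression
    with a simplified exact negative-binomial test (CPM filter, TMM
    normalization, BH correction), and relating predicted methylation to
    expression responsiveness through quantile-bin frequency and
    magnitude analyses. Includes a synthetic-data generator that
    emulates the statistical structure of such studies (mixture-
    distributed CpG targets, Markov-chain sequences realizing them,
    component-biased annotations, and negative-binomial counts whose
    differential-expression probability rises with CpG content) so the
    full analysis chain can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    edgeR,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
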