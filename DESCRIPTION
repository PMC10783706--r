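Package: quietnet
Title: Opinion Misperception and the Spiral of Silence on Scale-Free Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of opinion misperception in heterogeneous
    online communities. Generates scale-free networks by Molloy-Reed stub
    matching with a structural degree cutoff, places a hard-core minority of
    committed dissenters on nodes of a chosen degree, and runs two asynchronous
    opinion-expression dynamics: a probabilistic majority-conformity model and
    a goal-function (best-response) model in which agents may stay silent.
    Computes the misperception observables (average expressed opinion, local
    opinion climate, their decomposition), silencing statistics and power-law
    scaling fits, and orchestrates reproducible ensemble sweeps over the
    hard-core degree with tidy tabular outputs and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
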