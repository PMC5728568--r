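Package: neff
Title: Pairwise Entropy and Coding Efficiency of Prefrontal Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the information capacity and metabolic
    efficiency of neural population codes from trial-structured spike
    recordings. Spike counts are reduced to a two-state (above/below
    trial-mean) code; pairwise Shannon entropy, Pearson correlation and
    stimulus mutual information are estimated in closed form with
    first-order sampling-bias correction; coding efficiency is the slope
    of entropy change against the summed change in marginal firing
    probabilities, with bootstrap confidence intervals and a
    marginal-preserving permutation surrogate null for the coincidence
    structure. Includes a synthetic spike-session generator with
    shared-input correlations, threshold spike detection and PSTH
    utilities, and a two-neuron leaky integrate-and-fire model with
    shared afferent populations for exploring entropy/cost level curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    jsonlite,
    ggplot2,
    stats,
    grDevices,
    utils
Suggests:
    signal,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
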