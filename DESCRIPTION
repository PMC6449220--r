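Package: rtvalidity
Title: Validity of Inferences from Evidence-Accumulation Models of Response Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how well evidence-accumulation models of
    two-alternative forced-choice response times recover known experimental
    manipulations. Provides first-passage-time densities and simulators for the
    simple and full drift-diffusion model and the linear ballistic accumulator
    (LBA); a synthetic factorial speed/accuracy/bias experiment and the
    construction of the fourteen canonical two-condition pseudo-experiments;
    EZ, EZ2 and maximum-likelihood parameter estimation; estimate-based and
    heuristic inference of manipulated components; and scoring of inference
    tables against ground truth under planned and alternative scoring keys,
    including pairwise method agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
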