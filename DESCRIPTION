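Package: lacdfe
Title: Distribution of Fitness Effects in a Lac Operon Regulatory Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the distribution of fitness effects (DFE) of regulatory
    mutations in the Escherichia coli lactose-utilization network. A small ODE
    model of the lac operon (LacZ, LacY, total and free LacI, intracellular
    lactose) is solved to steady state and scored with a cost-benefit fitness
    function (lactose metabolized per unit time minus protein production cost).
    The package estimates the maximum attainable fitness over the mutable
    regulatory parameters, samples parameter sets at prescribed fractions of
    that maximum, perturbs single parameters with a multiplicative normal
    mutation kernel to build DFEs, classifies beneficial and deleterious
    mutations, fits exponential distributions to effect sizes by binned least
    squares, detects two-peaked deleterious DFEs, and quantifies pairwise
    epistasis between beneficial mutations, including diminishing-returns and
    sign epistasis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
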