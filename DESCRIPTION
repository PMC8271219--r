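Package: emtamr
Title: Coupled EMT-Estrogen-Receptor Network Dynamics and Drug-Resistance
    Population Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the gene regulatory network coupling
    epithelial-mesenchymal plasticity with estrogen-receptor signaling in
    ER+ breast cancer.  Generates ensembles of shifted-Hill ODE models over
    randomly sampled kinetic parameters, enumerates stable steady states,
    scores them along epithelial-mesenchymal and tamoxifen-resistance axes,
    classifies six phenotypes with Gaussian-mixture thresholds, and builds
    pseudo-potential landscapes from Euler-Maruyama trajectories.  A
    companion agent-based model of sensitive/resistant cell populations
    quantifies how non-genetic heterogeneity, stochastic phenotype
    switching, drug-induced plasticity and MET induction control tumor
    growth and extinction probability under anti-estrogen therapy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    mclust,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
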