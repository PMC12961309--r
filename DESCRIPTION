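Package: vtep
Title: Whole-Brain Jansen-Rit Simulation of TMS-Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates transcranial magnetic stimulation (TMS) evoked
    potentials (TEPs) with a delay-coupled network of Jansen-Rit neural
    mass models, one per brain region, coupled through a structural
    connectome with finite conduction delays. Source activity is projected
    to EEG channels through a lead-field matrix, structural connectivity
    can be fitted to a target TEP by stochastic gradient descent, and the
    inhibitory parameters of the model (inhibitory synaptic decay rate and
    number of inhibitory synapses) can be swept to emulate GABAergic
    deficits. TEP amplitude is quantified by the global mean field
    amplitude (GMFA) and parameter-response curves are characterised by
    linear, quadratic and exponential regression with minimum-SSE model
    selection. Includes a synthetic-data module generating connectomes,
    lead fields, stimulus maps and target TEPs so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
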