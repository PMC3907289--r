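Package: nercontrol
Title: Kinetic Modelling and Collective Rate Control of Nucleotide-Excision Repair
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative analysis of nucleotide-excision repair
    (NER) kinetics. Implements an analytical continuous-time Markov chain
    model of reversible multi-protein repair-complex assembly (mean repair
    times, completion curves, mono-exponential diagnostics), a mechanistic
    ordinary-differential-equation model of the NER pathway with five DNA
    intermediates and seven reversibly binding repair factors, maximum-
    likelihood parameter estimation with profile-likelihood confidence
    bounds, response-coefficient analysis of rate control, propagation of
    cell-to-cell variability, and a single-cell population simulator with
    synthetic-data generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    lhs,
    Matrix,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
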