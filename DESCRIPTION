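Package: synmax
Title: Infomax Recurrent Networks and the Emergence of Synaesthetic Mappings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent sigmoidal rate networks whose recurrent
    weights evolve by information-maximization (infomax) gradient learning,
    and analyses the conditions under which stable cross-modal (synaesthetic)
    mappings emerge between two sensory modalities with statistically
    independent inputs. Provides a two-unit model with a deterministic
    quadrature-based linear stability analysis of the learning dynamics
    (phase diagram over output variances, critical learning rate), and a
    two-hypercolumn model with cosine-tuned feedforward drive, population
    vector readout, and diagnostics for unidirectionality, mapping
    monotonicity, and critical slowing down of the network dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    jsonlite,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
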