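Package: elicitbn
Title: Expert Elicitation of Discrete Bayesian Networks by Delphi/RAND Consensus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates multi-expert elicitation responses into a discrete
    Bayesian network for clinical decision support. Implements the three-stage
    Delphi/RAND consensus pipeline (variable placement and ranking, structure
    grids with median/interpercentile-range fixing, probability elicitation
    with IPR-based outlier rejection), parsimonious conditional probability
    table models (leaky generalized noisy-OR, truncated-normal ranked nodes),
    exact inference by variable elimination, XMLBIF/BIF import and export,
    face-validity scenario checks, and a simulated expert panel generator for
    end-to-end validation against known ground-truth networks.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
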