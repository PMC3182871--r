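Package: sfmflow
Title: Multi-Time-Scale Functional Architectures as Structured Flows on Manifolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an autonomous dynamical architecture in which low-dimensional
    functional modes (structured flows on manifolds) are sequentially selected by a
    Winner-Take-All competition under competitive-queuing feedback and perturbed by
    brief excitable kicks, illustrated by cursive-handwriting word generation.
    Includes Excitator-class planar phase flows (monostable, bistable, limit cycle),
    numerical topology classification, fixed-step Euler-Maruyama integration with
    event logging, and a trial-ensemble phase-flow variability analysis that
    rearranges trials by phase-space nearest neighbours to recover the hidden
    operational signals (mode transitions and kicks) from the output alone.
License: MIT
Encoding: UTF-8
Imports: Rcpp, jsonlite, stats, utils, graphics, tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
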