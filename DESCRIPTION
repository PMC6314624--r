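Package: msknull
Title: Null-Space Projection Framework for Redundant Musculoskeletal Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models kinematic and dynamic redundancy of musculoskeletal systems
    with linear projection operators. Provides Moore-Penrose pseudoinverse and
    range/row/null-space projector construction, task- and muscle-space
    projections of the rigid-body equations of motion (task and muscle space
    inertia, bias terms, dynamically consistent inverses, null-space
    projectors), computation of the feasible muscle-force set as a convex
    polytope (halfspace construction, exact vertex enumeration with two
    independent backends, iterative interior sampling), per-muscle force
    variability and correlation summaries, joint reaction-force envelopes over
    the feasible set, and reflex (muscle-space) and reaching (task-space)
    controllers coupled to a deterministic mixed-dynamics simulator with
    sensory delay. Ships an analytic planar arm model with three degrees of
    freedom and nine muscles whose dynamics, moment arms and Jacobians are
    exact closed forms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    quadprog,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
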