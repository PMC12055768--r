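Package: spaffdyn
Title: Dyadic Affect Dynamics from SPAFF Observational Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing second-by-second Specific Affect Coding
    System (SPAFF) streams from two-person interactions such as
    psychotherapy sessions.  Per-second codes are weighted and summed into
    6-second window scores, sessions are summarised as seconds and
    percentages per code and per meta-state, affect usage is compared
    across sessions with one-sample Kolmogorov-Smirnov tests against
    fitted reference distributions, and the dyad is modelled as a pair of
    coupled difference equations with inertia, initial state,
    piecewise-linear influence functions and a repair term.  Phase
    portraits with analytically located fixed points, seeded synthetic
    generators with known ground truth, and plain-text session I/O make
    every stage testable without access to the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    rlang,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
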