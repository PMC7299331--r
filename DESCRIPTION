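Package: fibnet
Title: Fibration Symmetries and Logic Circuits in Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing signed, directed gene regulatory networks
    through the lens of graph fibration symmetry. Provides a discrete-time
    Boolean-threshold (Glass-Kauffman style) simulator for threshold circuits
    with closed-form solutions and an oscillation phase diagram for the
    frustrated feed-forward fiber; minimal balanced coloring (fibers), input
    trees with layer-count sequences and branching ratios, and quotient base
    graphs; finders for symmetric building blocks (autoregulation fibers,
    feed-forward fibers, Fibonacci fibers, n = 2 fibers) and broken-symmetry
    memory circuits (SR, clocked SR and JK flip-flop analogues); and a degree-
    and sign-preserving null model with Z-score statistics for circuit counts.
    Includes canonical circuit fixtures and a synthetic-network generator that
    plants known circuits in random background.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
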