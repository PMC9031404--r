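Package: rafnet
Title: Reflexively Autocatalytic Foodset-Derived (RAF) Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing catalytic reaction systems and
    detecting Reflexively Autocatalytic and Foodset-generated (RAF) sets:
    foodset closure, the maxRAF reduction, exhaustive subRAF enumeration,
    irreducible RAFs and co-RAFs, together with a brute-force certification
    oracle. Includes a cognitive instantiation in which mental representations
    with foodset provenance interact through catalysed representational
    redescription, social transmission between minds, inhibition, and RAF
    impact weights, plus a scripted therapist-client worked example. Provides
    generators for Kauffman's binary polymer model and phase-transition
    experiments on the emergence of autocatalytic sets, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
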