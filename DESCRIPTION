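Package: quadloop
Title: Detection and Analysis of Long-Loop RNA G-Quadruplexes in mRNA UTRs
Version: 0.1.0
Authors@R:
    person("quadloop", "maintainers", email = "quadloop@example.org",
           role = c("aut", "cre"))
Description: Tools for locating and characterising irregular RNA
    G-quadruplexes whose first or third loop is oversized (8-40 nt) in
    the untranslated regions of mRNAs. Provides a motif scanner with
    lazy (minimal) track/loop decomposition and a non-overlap rule, the
    consecutive-G over consecutive-C (cG/cC) fold-propensity score with
    25-nt flanking context, in-line probing K+/Li+ band-intensity ratio
    analysis with a threshold-based folded/unfolded call,
    dual-luciferase and qPCR fold-change statistics, seeded synthetic
    data generators with planted ground truth, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
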