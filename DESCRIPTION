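Package: cohsi
Title: Canonical Equilibrium Distributions of Discrete Systems Under
    Conserved Hartley-Shannon Information
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical-mechanics treatment of discrete token systems
    (proteins measured in amino acids, C source code measured in lexical
    tokens) whose total size and total Hartley-Shannon information are
    conserved. Provides the canonical equilibrium solutions for ordered
    (heterogeneous) and unordered (homogeneous) systems via the
    Ramanujan-corrected occupancy equation, exact brute-force ensemble
    enumeration to validate them, corpus readers (FASTA, UniProt flat file,
    ISO C90/C99 lexing), empirical distribution and protein-multiplicity
    construction, the two-stage power-law verdict (log-log least squares as
    the necessary test, discrete maximum-likelihood fitting with a
    Kolmogorov-Smirnov semiparametric bootstrap as the sufficiency test),
    and seeded synthetic corpus generators so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
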