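Package: obliphase
Title: Side-Channel-Resilient Reference-Based Haplotype Phasing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-based diploid haplotype phasing built from data-oblivious
    components. A phased reference panel is block-compressed to its unique
    haplotypes (an M3VCF-style encoding), per-block positional Burrows-Wheeler
    transforms arranged as prefix trees support oblivious insertion of the
    current phase estimate and longest-suffix-match neighbour selection, and a
    diploid Li-Stephens hidden Markov model over a genotype graph is evaluated
    entirely in dynamically scaled fixed-point arithmetic. All secret-dependent
    computation is routed through data-oblivious primitives (linear-scan ORAM,
    bitonic sorting networks, oblivious filtering, deterministic multiplexers,
    constant-time long division) whose memory-access traces are
    input-independent by construction and testable through a trace-capture
    harness. Includes a synthetic mosaic-panel generator and switch-error-rate
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
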