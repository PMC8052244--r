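Package: ccrsolve
Title: Resolution and Interpretation of Complex Chromosomal Rearrangements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving and interpreting ultra-complex germline
    chromosomal rearrangements (CCRs) from curated breakpoint-junction tables:
    reconstruction of derivative chromosomes by walking fragment-junction
    chains, nucleotide-level junction signature classification (microhomology,
    templated and non-templated insertions, junction deletions), exact binomial
    and Monte Carlo tests of fragment distribution, fusion orientation and
    intragenic breakpoint enrichment, a decision-table classifier for the
    mechanism of formation (chromothripsis, chromoplexy, breakage-fusion-bridge,
    replicative), meiotic segregation analysis for multi-rearrangement carriers,
    topologically associated domain (TAD) disruption summaries, and benchmarking
    of multi-technology structural-variant call sets against a confirmed
    junction truth set. A mechanism-specific CCR simulator generates fully
    annotated synthetic rearrangements and technology-degraded call sets so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    VariantAnnotation
Config/testthat/edition: 3
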