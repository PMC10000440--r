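Package: noncneo
Title: Proteogenomic Discovery of Neoantigens from Noncoding Somatic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A proteogenomics pipeline for predicting candidate neoantigens
    that arise from somatic variants in noncoding genomic regions. Somatic
    variant calls are filtered to PASS noncoding mutations, a +/-100 nt
    mutant sequence context is extracted around each variant and translated
    in all six reading frames, and stop-free mutation-containing fragments
    are assembled into a customized proteomic search database (reference
    proteome, laboratory contaminants, mutant peptides, and pseudo-reversed
    tryptic decoys). Peptides confirmed by a mass-spectrometry search are
    matched back to mutant entries, mutated 8-11-mers are scored against
    patient HLA class I alleles through a pluggable percentile-rank
    predictor, candidates with a percentile rank below 2 are retained, and
    a Smith-Waterman homology screen against a set of experimentally
    immunogenic peptides flags high-confidence neoantigens. Deterministic
    synthetic fixtures with planted ground truth make every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    optparse
Config/testthat/edition: 3
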