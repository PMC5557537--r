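Package: tandemsim
Title: Tandem-Simulation Prediction of Read Mapping Qualities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligner-agnostic recalibration of SAM mapping qualities by tandem
    simulation. The package learns an input model (per-alignment templates of
    strand, quality string, and CIGAR/MD mutation pattern, subsampled with
    reservoir sampling) from an aligned read set, simulates truth-labeled
    tandem reads that mimic the inputs, trains per-category random-forest
    models on the tandem alignments, rewrites the MAPQ field of the original
    alignments with the model's predictions, and evaluates competing
    mapping-quality assignments with cumulative-incorrect / cumulative
    squared-error difference curves and their RCA and RCE summaries. A
    self-contained fixture layer (synthetic repetitive genome generator, read
    simulator, and a seed-and-extend toy aligner that emits per-alignment
    feature tags) allows the whole pipeline to run end-to-end without
    external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ranger,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
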