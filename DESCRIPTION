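Package: ezgkit
Title: Early Zygotic Gene Discovery from Embryonic RNA-Seq Time Courses
Version: 0.1.0
Authors@R:
    person("Jacob", "Hartmann", email = "jhartmann@example.org", role = c("aut", "cre"))
Description: Tools to identify early zygotic genes (EZGs) from unreplicated
    embryonic RNA-seq time courses spanning the maternal-zygotic transition.
    Implements presence/absence temporal classification of transcripts,
    the MA-plot-based random-sampling (MARS) significance test for
    unreplicated count pairs with Storey q-values, length- and
    depth-normalized expression (reads per kilobase per million),
    intronless-gene enrichment tests, discovery of overrepresented
    degenerate (IUPAC) promoter motifs by beam search with greedy
    degeneration, position weight matrix alignment with empirical
    permutation E-values, a seeded synthetic-data generator for
    validation, and a command-line pipeline tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    BiocGenerics,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
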