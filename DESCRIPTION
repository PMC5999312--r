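Package: panhe
Title: Gene Presence/Absence Variation and Homoeologous Exchange Detection
    in Allopolyploid Pangenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Depth-threshold gene presence/absence (PAV) calling from
    per-base read-depth tracks, detection of homoeologous exchanges (HEs)
    from runs of absent genes supported by homology and coverage-doubling
    evidence, core/variable classification of genes and gene families,
    bootstrap dendrograms from binary PAV matrices, and pangenome/core-genome
    growth-curve modelling with power-law and exponential fits. Includes a
    synthetic allotetraploid data generator (paired A/C subgenome
    chromosomes, homoeologous gene pairs, HE events with terminal bias and
    C-to-A directional bias, Poisson read depth) so the whole pipeline can
    be exercised without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ape,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    ggplot2
Config/testthat/edition: 3
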