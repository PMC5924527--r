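Package: genomeprep
Title: Preprocessing and Quality Control for Short-Read Genome Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable preprocessing and quality-control stages for de novo
    short-read genome assembly projects: mate-pair linker clipping with a
    continuous-core alignment rule (Cre-Lox and Nextera junctions), Roche
    454 linker splitting with reverse-segment trimming, canonical k-mer
    spectrum construction and genome-size estimation, alignment-gated
    insert-size estimation, assembly statistics (N50/L50, cutoff tables,
    completeness percentages), GATK-style variant hard filtering with
    repeat-mask subtraction and heterozygosity densities, and
    homology-hint truncation for gene prediction. Seeded simulators
    generate every input class with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    graphics,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
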