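Package: speedcongenics
Title: Marker-Assisted Backcross Genotyping Analysis and Simulation for
    Speed Congenics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for marker-assisted backcross ("speed congenics")
    experiments in mice. From multi-sample SNP genotype calls the package
    identifies diagnostic markers between a donor and a recipient strain,
    computes per-sample congenic-ancestry summaries (percent recipient
    alleles, genotyping success) to guide breeder selection, reports the
    chromosomal distribution and spacing of marker sets, and performs
    read-depth quality control. A bundled backcross simulator models
    diploid genomes as ancestry-labelled chromosome segments with
    Poisson-crossover meiosis and replays a multi-generation
    marker-assisted breeding scheme, providing ground truth against which
    the whole analysis workflow is validated.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: Genetics, SNP, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
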