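Package: screenmap
Title: Mapping-by-Sequencing for Forward Genetic Screens with Pooled Progeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to locate phenotype-causing, EMS-induced point mutations
    from pooled whole-genome sequencing of selected progeny. Candidate SNPs
    (high-quality, absent from the parental strain) are counted in
    sequential 1 Mb windows and the density peak is reported as the
    candidate region, using homozygous SNPs for viable mutants or
    heterozygous SNPs (Het-Map) for sterile mutants mapped through pooled
    carrier progeny. Includes a forward simulator of the screen pedigree
    (EMS mutagenesis, Mendelian segregation, Haldane recombination,
    backcrossing, pooled binomial read sampling) that emits VCF variant
    calls with known ground truth, plus minimal VCF/BED/TSV readers and
    writers, diagnostic plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    optparse,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
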