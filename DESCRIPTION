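Package: flockdiv
Title: Genomic Diversity, Runs of Homozygosity and Population Structure
    from SNP Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for genome-wide characterization of livestock
    populations from medium-density SNP array data. Reads and writes PLINK
    PED/MAP and BED/BIM/FAM files, applies the standard quality-control
    cascade (autosome, call-rate and minor-allele-frequency filters, windowed
    LD pruning), computes per-locus and summary diversity indices (observed
    and expected heterozygosity, FIS, MAF), detects runs of homozygosity with
    the consecutive-runs method and derives length classes, per-chromosome
    summaries and the genomic inbreeding coefficient FROH, scans SNP-in-run
    incidence for homozygosity islands, estimates historical effective
    population size from binned LD decay and contemporary effective
    population size with the bias-corrected linkage-disequilibrium method,
    and quantifies between-population structure through identity-by-state
    distances with classical multidimensional scaling, Weir-Cockerham FST,
    Reynolds distances and neighbor-joining trees. Includes seeded synthetic
    genotype generators (Balding-Nichols structure, forward Wright-Fisher
    with recombination, planted homozygous segments) with ground-truth
    records for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
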