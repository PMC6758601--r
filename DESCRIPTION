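Package: pentad
Title: Partitioned Five-Taxon D-Statistics, Quartet Sampling, and RAD-Seq
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and localise introgression in clade-level
    phylogenies built from RAD-seq data.  Implements frequency-weighted
    partitioned five-taxon ABBA-BABA statistics (D1, D2, D12) over pooled
    clades with locus-bootstrap Z-scores, Quartet Sampling branch and taxon
    support metrics (QC, QD, QI, QF), and a multispecies-coalescent
    simulator with admixture pulses, Jukes-Cantor sequence evolution,
    RAD-style locus dropout and minimum-samples-per-locus filtering, so
    every stage of the analysis can be exercised against data with known
    ground truth.  Readers and writers are provided for VCF, FASTA,
    relaxed PHYLIP, Newick and clade-assignment tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    igraph,
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
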