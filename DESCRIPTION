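Package: sweepwatch
Title: Haplotype-Based Selective Sweep Scans Around Candidate Causal Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scanning targeted resequencing regions for signatures
    of recent positive selection around a candidate causal variant, built for
    phased biallelic haplotype panels such as those produced by targeted
    capture of melanism loci in wild felids. Reads phased VCF, sample
    metadata and window (fosmid) definitions; stratifies chromosomes by the
    allele carried at the core site; computes windowed nucleotide diversity
    with standard errors, haplotype counts, extended haplotype homozygosity
    (EHH) curves and haplotype bifurcation trees; performs
    genotype-phenotype association tests and Hardy-Weinberg phenotype
    frequency predictions; and summarises capture-enrichment arithmetic.
    Includes a founder-haplotype sweep simulator with ground truth so every
    stage of the scan can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
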