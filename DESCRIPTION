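Package: sexchromevol
Title: Detection of Sex Chromosomes and Reconstruction of Their Turnover
    Dynamics Across a Species Radiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A workflow for identifying sex-linked chromosomal regions in
    closely related species and reconstructing sex-chromosome evolution on a
    time-calibrated phylogeny.  Three complementary scans detect sex linkage:
    a tribe-wise sliding-window accumulation test for sex-specific SNPs in
    whole-genome genotype data with permutation-derived significance
    thresholds; a per-SNP sex association scan followed by genotype
    clustering; and a species-level scan of sexed replicate transcriptome
    allele counts.  Calls from the three scans are integrated into permissive
    and stringent call sets.  Downstream, Mk-model fitting, stochastic
    character mapping, turnover-point detection, heterogamety transition
    analysis, a recruitment randomization test, and phylogenetic generalized
    least squares quantify the tempo and mode of sex-chromosome evolution.
    A synthetic-data module generates genotype, allele-count, and character
    history data with planted truth so the full pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    cluster,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    vcfR,
    nlme,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
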