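#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohorts with planted truth.
# Writes the WGS genotypes as VCF, the sample panel and LG tables as TSV,
# the replicate transcriptome allele counts as TSV, and a time tree with a
# simulated heterogamety history.

source("analysis/00_setup.R")

sim <- simulate_wgs_cohort(panel6, lgs_wgs, truth6, n_sites_per_lg = 4000,
                           missing_frac = 0.02, seed = ROOT_SEED)
write_cohort_vcf(sim$vt, file.path(DATA, "cohort.vcf"))
utils::write.table(panel6, file.path(DATA, "panel.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(lgs_wgs, file.path(DATA, "lgs_wgs.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(lgs_rna, file.path(DATA, "lgs_rna.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

rna <- simulate_rna_counts(truth_rna, lgs_rna, "sp5", n_snps = 2000,
                           depth_mean = 10, seed = ROOT_SEED)
write_allele_counts(rna$counts, file.path(DATA, "rna_counts_sp5.tsv"))

set.seed(ROOT_SEED)
tree <- ape::rcoal(16)
tree$edge.length <- tree$edge.length * 10 /
  max(ape::node.depth.edgelength(tree)[1:16])
tree$tip.label <- paste0("t", 1:16)
ape::write.tree(tree, file.path(DATA, "timetree.nwk"))

jsonlite::write_json(list(truth_wgs = truth6$species,
                          truth_rna = truth_rna$species,
                          seed = ROOT_SEED),
                     file.path(DATA, "truth.json"), auto_unbox = TRUE)

cat("Simulated:", n_sites(sim$vt), "WGS sites x", nrow(panel6),
    "individuals;", nrow(rna$counts$snps), "RNA SNPs (",
    sum(rna$planted), "planted );", length(tree$tip.label),
    "tree tips.\n")
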