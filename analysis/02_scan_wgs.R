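#!/usr/bin/env Rscript
# Stage 2: tribe-wise WGS accumulation scan (sex-specific SNP windows,
# permutation thresholds, outlier regions, species attribution) on the
# stored cohort.

source("analysis/00_setup.R")

panel <- read_panel(file.path(DATA, "panel.tsv"))
vt <- read_genotype_vcf(file.path(DATA, "cohort.vcf"), panel)
vt <- apply_genotype_filters(mask_around_indels(vt))

res <- scan_wgs(vt, panel, n_perm = 100, seed = ROOT_SEED, masks = NULL)

write_tsv(res$windows, "wgs_windows.tsv")
write_tsv(res$regions, "wgs_regions.tsv")
write_tsv(res$calls, "wgs_calls.tsv")

cat("Permutation threshold |XY-ZW|/species:",
    round(res$thresholds$max_abs_diff_norm, 2), "\n")
cat("Outlier regions:", nrow(res$regions), "\n")
cat("Species calls:\n")
print(res$calls[, c("species_id", "lg_id", "system")])
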