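#!/usr/bin/env Rscript
# Stage 3: per-SNP sex association (trend test) plus genotype clustering
# of the top SNPs, resolving carrier species and heterogamety.

source("analysis/00_setup.R")

panel <- read_panel(file.path(DATA, "panel.tsv"))
vt <- read_genotype_vcf(file.path(DATA, "cohort.vcf"), panel)
vt <- apply_genotype_filters(mask_around_indels(vt))

res <- scan_assoc(vt, panel, mode = "top_k", k = 100)

write_tsv(res$assoc, "assoc_snps.tsv")
write_tsv(res$calls, "assoc_calls.tsv")

cat("Top association -log10(p):",
    round(max(res$assoc$neglog10_p), 2), "\n")
cat("Species calls:\n")
print(res$calls)
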