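#!/usr/bin/env Rscript
# Stage 4: species-level transcriptome scan (sex-biased SNP filter,
# sex-exclusive classification, window outliers, heterogamety decision,
# candidate LGs).

source("analysis/00_setup.R")

act <- read_allele_counts(file.path(DATA, "rna_counts_sp5.tsv"))
lgs <- lg_table(file.path(DATA, "lgs_rna.tsv"))

res <- scan_rna(act, lgs, species_id = "sp5")

write_tsv(res$windows, "rna_windows.tsv")
write_tsv(res$calls, "rna_calls.tsv")
if (!is.null(res$per_lg)) write_tsv(res$per_lg, "rna_per_lg.tsv")

cat("Heterogamety:", res$system, "( paired test p =",
    signif(res$p_value, 3), ")\n")
cat("Candidate LG(s):", paste(res$candidate_lgs, collapse = ", "), "\n")
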