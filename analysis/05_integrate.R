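#!/usr/bin/env Rscript
# Stage 5: merge approach-level evidence into permissive and stringent
# species-level call sets and summarise heterogamety and recruitment.

source("analysis/00_setup.R")

a1 <- utils::read.table(file.path(RESULTS, "assoc_calls.tsv"),
                        header = TRUE, sep = "\t")
a2 <- utils::read.table(file.path(RESULTS, "wgs_calls.tsv"),
                        header = TRUE, sep = "\t")
a3 <- utils::read.table(file.path(RESULTS, "rna_calls.tsv"),
                        header = TRUE, sep = "\t")

cs <- integrate_calls(a1 = a1, a2 = a2, a3 = a3,
                      all_species = unique(panel6$species_id))

write_tsv(cbind(flavor = "permissive", cs$permissive$calls),
          "calls_permissive.tsv")
write_tsv(cbind(flavor = "stringent", cs$stringent$calls),
          "calls_stringent.tsv")

sm_p <- summarize_calls(cs$permissive)
sm_s <- summarize_calls(cs$stringent)
jsonlite::write_json(
  list(permissive = sm_p[c("n_xy", "n_zw", "pct_xy")],
       stringent = sm_s[c("n_xy", "n_zw", "pct_xy")],
       per_lg_permissive = as.list(sm_p$per_lg)),
  file.path(RESULTS, "call_summary.json"), auto_unbox = TRUE)

cat("Permissive calls:", nrow(cs$permissive$calls),
    "( XY:", sm_p$n_xy, "ZW:", sm_p$n_zw, ")\n")
cat("Stringent calls:", nrow(cs$stringent$calls), "\n")
cat("No signal:", paste(cs$permissive$no_signal, collapse = ", "), "\n")
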