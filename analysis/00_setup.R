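# Shared study design for the analysis workflow.
#
# One tribe of six species (one male + one female genome each), four of
# which share a planted XY system on LG05 (region 200-500 kb, fully
# differentiated); a 23-LG reference for the transcriptome scan; and a
# 16-tip time tree for the phylogenetic stages.  All drivers source this
# file and write under results/.

suppressMessages(library(sexchromevol))

RESULTS <- "results"
DATA <- file.path(RESULTS, "data")
dir.create(DATA, showWarnings = FALSE, recursive = TRUE)

ROOT_SEED <- 1L

panel6 <- sample_panel(data.frame(
  individual_id = paste0("sp", rep(1:6, each = 2), c("_m", "_f")),
  species_id = paste0("sp", rep(1:6, each = 2)),
  tribe_id = "T1",
  sex = rep(c("male", "female"), 6)))

lgs_wgs <- lg_table(data.frame(lg_id = c("LG05", "LG09"),
                               length_bp = rep(800000L, 2)))

lgs_rna <- lg_table(data.frame(lg_id = paste0("LG", sprintf("%02d", 1:23)),
                               length_bp = rep(2000000L, 23)))

truth6 <- sim_truth(data.frame(
  species_id = paste0("sp", 1:6),
  sex_lg = c(rep("LG05", 4), NA, NA),
  system = c(rep("XY", 4), "none", "none"),
  region_start = 200001L, region_end = 500000L,
  differentiation = c(rep(1, 4), NA, NA)), seed = ROOT_SEED)

# a species-specific ZW system carried by sp5 only: detectable by the
# transcriptome scan but invisible to the tribe-wise WGS scans
truth_rna <- sim_truth(data.frame(
  species_id = "sp5", sex_lg = "LG07", system = "ZW",
  region_start = 100001L, region_end = 900000L,
  differentiation = 1), seed = ROOT_SEED)

write_tsv <- function(x, name) {
  utils::write.table(x, file.path(RESULTS, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(RESULTS, name))
}
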