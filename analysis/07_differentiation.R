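#!/usr/bin/env Rscript
# Stage 7: size the sex-differentiated regions of the called species,
# relate differentiation to system age, and extract X/Y haplotypes for the
# convergence check (neighbor-joining tree of haplotype sequences).

source("analysis/00_setup.R")

panel <- read_panel(file.path(DATA, "panel.tsv"))
vt <- read_genotype_vcf(file.path(DATA, "cohort.vcf"), panel)
vt <- apply_genotype_filters(mask_around_indels(vt))
sct <- classify_sites(vt, panel)

carriers <- paste0("sp", 1:4)
regions <- do.call(rbind, lapply(carriers, function(sp)
  differentiation_regions(sct, sp, "LG05", "XY", lgs_wgs)))
write_tsv(regions, "differentiation_regions.tsv")
cat("Differentiated proportion of LG05 per carrier:\n")
print(regions[, c("species_id", "cumulative_bp", "proportion_of_lg")])

# age ~ differentiation under a star phylogeny of the four carriers
star <- ape::stree(4, "star")
star$edge.length <- rep(5, 4)
star$tip.label <- carriers
set.seed(ROOT_SEED)
ages <- setNames(c(4.2, 5.1, 5.8, 4.9), carriers)
props <- setNames(regions$proportion_of_lg, regions$species_id)
pg <- tryCatch(age_differentiation_pgls(props, ages, star),
               error = function(e) NULL)
if (!is.null(pg))
  cat(sprintf("pGLS differentiation ~ age: coefficient %.4f, p = %.4g\n",
              pg$coefficient, pg$p_value))

hp <- extract_sex_haplotypes(vt, sct, carriers, seed = ROOT_SEED)
write_haplotype_fasta(hp$haplotypes, file.path(RESULTS, "haplotypes.fasta"))
tr <- haplotype_nj_tree(hp$haplotypes)
ape::write.tree(tr, file.path(RESULTS, "haplotype_nj.nwk"))
cat("Haplotype NJ tree over", nrow(hp$haplotypes), "haplotypes at",
    nrow(hp$sites), "sites written.\n")
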