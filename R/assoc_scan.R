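# Approach 1: per-SNP sex association across a tribe, followed by genotype
# clustering of the most strongly associated SNPs to resolve which species
# carry the signal and with which heterogamety.

#' Per-SNP sex association (Cochran-Armitage trend test)
#'
#' Tests, at every biallelic SNP, for a linear trend of genotype dosage
#' (0/1/2 alternative alleles) with sex.  Population-structure correction
#' is deliberately omitted (synthetic cohorts carry none).  Missing
#' genotypes are dropped per site; monomorphic sites get p = 1.
#'
#' @param vt a filtered `variant_table`.
#' @param panel matching `sample_panel` (needs >= 2 males and >= 2 females).
#' @return data.frame: `lg_id`, `pos`, `p_value`, `neglog10_p`.
#' @export
snp_sex_association <- function(vt, panel) {
  sex <- panel$sex[match(colnames(vt$a1), panel$individual_id)]
  if (sum(sex == "male") < 2L || sum(sex == "female") < 2L)
    stop("need at least two males and two females")
  g <- genotype_codes(vt)
  y <- as.integer(sex == "male")
  p <- vapply(seq_len(nrow(g)), function(i)
    ca_trend_p(g[i, ], y), 1.0)
  data.frame(lg_id = vt$sites$lg_id, pos = vt$sites$pos,
             p_value = p, neglog10_p = -log10(p),
             stringsAsFactors = FALSE)
}

# Cochran-Armitage trend statistic with scores 0/1/2, chi-squared 1 df
ca_trend_p <- function(g, y) {
  ok <- !is.na(g)
  g <- g[ok]; y <- y[ok]
  n <- length(g)
  if (n < 4L || length(unique(g)) < 2L || length(unique(y)) < 2L)
    return(1)
  num <- sum((y - mean(y)) * g)
  den <- sum((y - mean(y))^2) * sum((g - mean(g))^2) / n
  if (den <= 0) return(1)
  stat <- num^2 / den
  stats::pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' Cluster genotypes at top sex-associated SNPs and call species
#'
#' Selects either the `k` most significant SNPs (broad, chromosome-scale
#' signals) or all SNPs above a -log10(p) cutoff (narrow peaks), clusters
#' all individuals' genotypes at the selected SNPs with the shared
#' Gower/divisive engine, and calls a species XY when (i) its male/female
#' pair separates at the two-cluster cut and (ii) the male is
#' heterozygous-enriched at the selected SNPs (fraction of selected SNPs
#' with male heterozygous and female homozygous above `het_enrich_min`);
#' ZW mirrored.
#'
#' @param ar association results from [snp_sex_association()].
#' @param vt the `variant_table` tested.
#' @param panel matching `sample_panel`.
#' @param mode `"top_k"` or `"threshold"`.
#' @param k number of SNPs in `top_k` mode.
#' @param logp_min -log10(p) cutoff in `threshold` mode.
#' @param het_enrich_min heterozygous-enrichment cutoff (explicit stand-in
#'   for visual heatmap inspection).
#' @return list with `selected` (row indices of selected SNPs) and `calls`
#'   (data.frame `species_id`, `tribe_id`, `lg_id`, `system`, `evidence`);
#'   `lg_id` is the majority LG among the species' supporting SNPs.
#' @export
cluster_top_genotypes <- function(ar, vt, panel,
                                  mode = c("top_k", "threshold"),
                                  k = 100L, logp_min = 3,
                                  het_enrich_min = 0.8) {
  mode <- match.arg(mode)
  stopifnot(nrow(ar) > 0L)
  if (mode == "top_k") {
    if (nrow(ar) < k) {
      warning("fewer SNPs than k; using all ", nrow(ar))
      k <- nrow(ar)
    }
    sel <- order(ar$p_value)[seq_len(k)]
  } else {
    sel <- which(ar$neglog10_p > logp_min)
  }
  empty <- data.frame(species_id = character(), tribe_id = character(),
                      lg_id = character(), system = character(),
                      evidence = character())
  if (length(sel) == 0L) return(list(selected = sel, calls = empty))
  g <- genotype_codes(vt)[sel, , drop = FALSE]
  cl <- divisive_two_cut(gower_genotype_dist(t(g)))
  calls <- list()
  for (sp in unique(panel$species_id)) {
    p <- panel[panel$species_id == sp, ]
    male <- p$individual_id[p$sex == "male"][1L]
    female <- p$individual_id[p$sex == "female"][1L]
    if (is.na(male) || is.na(female)) next
    if (!pair_separates(cl, male, female)) next
    gm <- g[, male]; gf <- g[, female]
    ok <- !is.na(gm) & !is.na(gf)
    if (!any(ok)) next
    fr_xy <- mean(gm[ok] == 1L & gf[ok] != 1L)
    fr_zw <- mean(gf[ok] == 1L & gm[ok] != 1L)
    system <- if (fr_xy > het_enrich_min) "XY"
      else if (fr_zw > het_enrich_min) "ZW" else NA_character_
    if (is.na(system)) next
    supp <- if (system == "XY") which(gm == 1L & gf != 1L)
      else which(gf == 1L & gm != 1L)
    lg <- names(sort(table(ar$lg_id[sel][supp]), decreasing = TRUE))[1L]
    calls[[length(calls) + 1L]] <- data.frame(
      species_id = sp, tribe_id = p$tribe_id[1L], lg_id = lg,
      system = system, evidence = "A1")
  }
  list(selected = sel,
       calls = if (length(calls) > 0L) do.call(rbind, calls) else empty)
}

#' Run the full association scan for one tribe
#'
#' @inheritParams cluster_top_genotypes
#' @param vt filtered `variant_table`.
#' @param panel matching `sample_panel`.
#' @return list with `assoc` (per-SNP results) and `calls`.
#' @export
scan_assoc <- function(vt, panel, mode = "top_k", k = 100L, logp_min = 3,
                       het_enrich_min = 0.8) {
  ar <- snp_sex_association(vt, panel)
  ct <- cluster_top_genotypes(ar, vt, panel, mode = mode, k = k,
                              logp_min = logp_min,
                              het_enrich_min = het_enrich_min)
  list(assoc = ar, selected = ct$selected, calls = ct$calls)
}
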