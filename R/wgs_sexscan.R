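# Approach 2: tribe-wise accumulation test for sex-specific SNPs.
# Per species, every site is recoded as XY / ZW / nosex / noinfo from the
# male-female genotype pair; class counts are summed in 10-kb windows
# sliding by 2 kb, compared against genome-wide expectations, and screened
# with tribe-wise permutation thresholds before regions are called and
# attributed to species by genotype clustering.

CLASS_LEVELS <- c("XY", "ZW", "nosex", "noinfo")

#' Classify sites per species as XY / ZW / nosex / noinfo
#'
#' Uses the designated male/female genome pair of each species (the first
#' male and first female in the panel).  A site is `XY` when the male is
#' heterozygous and the female homozygous, `ZW` in the mirrored case,
#' `noinfo` when either genotype is missing, and `nosex` otherwise
#' (identical genotypes, and the neither-heterozygous case of opposite
#' homozygotes, logged in attribute `n_opposite_hom`).
#'
#' @param vt a filtered `variant_table`.
#' @param panel a `sample_panel`; species lacking one sex are skipped with
#'   a warning.
#' @return object of class `site_class_table`: site coordinates plus an
#'   integer class matrix (sites x species, levels XY/ZW/nosex/noinfo).
#' @export
classify_sites <- function(vt, panel) {
  g <- genotype_codes(vt)
  species <- unique(panel$species_id)
  pairs <- lapply(species, function(sp) {
    p <- panel[panel$species_id == sp, ]
    list(male = p$individual_id[p$sex == "male"][1L],
         female = p$individual_id[p$sex == "female"][1L])
  })
  ok <- vapply(pairs, function(p) !is.na(p$male) && !is.na(p$female), TRUE)
  if (any(!ok))
    warning("skipping species lacking a male/female pair: ",
            paste(species[!ok], collapse = ", "))
  species <- species[ok]
  pairs <- pairs[ok]
  cls <- matrix(NA_integer_, nrow(g), length(species),
                dimnames = list(NULL, species))
  n_opp <- 0L
  for (k in seq_along(species)) {
    gm <- g[, pairs[[k]]$male]
    gf <- g[, pairs[[k]]$female]
    ci <- rep(3L, length(gm))                       # nosex default
    ci[is.na(gm) | is.na(gf)] <- 4L                 # noinfo
    ci[!is.na(gm) & !is.na(gf) & gm == 1L & gf != 1L] <- 1L  # XY
    ci[!is.na(gm) & !is.na(gf) & gf == 1L & gm != 1L] <- 2L  # ZW
    n_opp <- n_opp + sum(!is.na(gm) & !is.na(gf) &
                           ((gm == 0L & gf == 2L) | (gm == 2L & gf == 0L)))
    cls[, k] <- ci
  }
  structure(list(sites = vt$sites[, c("lg_id", "pos")],
                 cls = cls, species = species, panel = panel),
            class = "site_class_table", n_opposite_hom = n_opp)
}

#' Per-species class counts of a site-class table
#' @param sct a `site_class_table`.
#' @return matrix species x class.
#' @export
class_counts <- function(sct) {
  t(apply(sct$cls, 2L, tabulate, nbins = 4L)) |>
    `dimnames<-`(list(sct$species, CLASS_LEVELS))
}

# per-site counts of XY / ZW / nosex over species (noinfo excluded)
site_counts <- function(cls) {
  cbind(xy = rowSums(cls == 1L),
        zw = rowSums(cls == 2L),
        nosex = rowSums(cls == 3L))
}

# map each site to the sliding-window start indices that cover it
window_index <- function(pos, window, step) {
  jmin <- pmax(0L, as.integer(ceiling((pos - window) / step)))
  jmax <- as.integer(floor((pos - 1) / step))
  list(jmin = jmin, jmax = jmax, n = jmax - jmin + 1L)
}

#' Sliding-window class sums and expectations
#'
#' Sums species-site class counts in sliding windows (default 10 kb,
#' step 2 kb, grid anchored at position 1 per LG; windows with no called
#' site are dropped).  Expected counts per window are the genome-wide class
#' fractions (over called species-sites) multiplied by the number of called
#' sites in the window.
#'
#' @param sct a `site_class_table`.
#' @param window,step window width and slide, bp.
#' @return a `data.table` with one row per window: observed and expected
#'   XY/ZW/nosex counts, `xy_zw_diff` and its per-species normalisation.
#' @export
window_stats <- function(sct, window = 10000L, step = 2000L) {
  if (nrow(sct$sites) == 0L) stop("empty site class table")
  sc <- site_counts(sct$cls)
  window_stats_from_counts(sct$sites, sc, length(sct$species), window, step)
}

window_stats_from_counts <- function(sites, sc, n_species,
                                     window = 10000L, step = 2000L) {
  wi <- window_index(sites$pos, window, step)
  site_rep <- rep(seq_len(nrow(sites)), wi$n)
  jj <- sequence(wi$n) - 1L + rep(wi$jmin, wi$n)
  dt <- data.table::data.table(
    lg_id = sites$lg_id[site_rep], j = jj,
    xy = sc[site_rep, "xy"], zw = sc[site_rep, "zw"],
    nosex = sc[site_rep, "nosex"])
  w <- dt[, .(obs_xy = sum(xy), obs_zw = sum(zw), obs_nosex = sum(nosex)),
          by = .(lg_id, j)]
  w[, start := j * step + 1L]
  w[, end := start + window - 1L]
  w[, n_called := obs_xy + obs_zw + obs_nosex]
  w <- w[n_called > 0L]
  tot <- colSums(sc)
  frac <- tot / sum(tot)
  w[, exp_xy := frac[["xy"]] * n_called]
  w[, exp_zw := frac[["zw"]] * n_called]
  w[, exp_nosex := frac[["nosex"]] * n_called]
  w[, xy_zw_diff := obs_xy - obs_zw]
  w[, xy_zw_diff_norm := xy_zw_diff / n_species]
  data.table::setorder(w, lg_id, start)
  w[, j := NULL]
  w[]
}

# vectorised Pearson chi-squared p for 2x3 tables: rbind(obs, round(exp))
pearson_p_2x3 <- function(obs, expd) {
  expd <- round(expd)
  tab_tot <- rowSums(obs) + rowSums(expd)
  p_row_obs <- rowSums(obs) / tab_tot
  stat <- numeric(nrow(obs))
  for (c in 1:3) {
    colsum <- obs[, c] + expd[, c]
    e1 <- colsum * p_row_obs
    e2 <- colsum * (1 - p_row_obs)
    s1 <- ifelse(e1 > 0, (obs[, c] - e1)^2 / e1, 0)
    s2 <- ifelse(e2 > 0, (expd[, c] - e2)^2 / e2, 0)
    stat <- stat + s1 + s2
  }
  stats::pchisq(stat, df = 2L, lower.tail = FALSE)
}

designate_windows <- function(w) {
  w[, designation := data.table::fcase(
    obs_xy > exp_xy & obs_zw > exp_zw, "ambiguous",
    obs_xy > exp_xy & obs_zw < exp_zw, "XY",
    obs_zw > exp_zw & obs_xy < exp_xy, "ZW",
    default = "nosex")]
  w
}

#' Test windows against genome-wide expectations
#'
#' Each window's observed XY/ZW/nosex counts are compared to the (rounded)
#' expected counts in a 2x3 contingency table, by Fisher's exact test when
#' the table total is small enough and by a Pearson chi-squared test
#' otherwise.  Windows are designated XY, ZW, ambiguous (both classes above
#' expectation; not considered further) or nosex; p-values are reported for
#' XY/ZW windows.
#'
#' @param w window table from [window_stats()].
#' @param method `"fisher"` (with automatic chi-squared fallback for large
#'   tables) or `"chi2"`.
#' @param fisher_max_total largest table total passed to the exact test.
#' @return the window table with `designation` and `p_value` columns.
#' @export
test_windows <- function(w, method = c("fisher", "chi2"),
                         fisher_max_total = 10000L) {
  method <- match.arg(method)
  w <- designate_windows(data.table::copy(w))
  w[, p_value := NA_real_]
  idx <- which(w$designation %in% c("XY", "ZW"))
  if (length(idx) == 0L) return(w[])
  obs <- as.matrix(w[idx, .(obs_xy, obs_zw, obs_nosex)])
  expd <- as.matrix(w[idx, .(exp_xy, exp_zw, exp_nosex)])
  if (method == "chi2") {
    w$p_value[idx] <- pearson_p_2x3(obs, expd)
    return(w[])
  }
  re <- round(expd)
  tot <- rowSums(obs) + rowSums(re)
  big <- tot > fisher_max_total
  if (any(big)) {
    warning(sum(big), " window table(s) too large for the exact test; ",
            "falling back to Pearson chi-squared")
    w$p_value[idx[big]] <- pearson_p_2x3(obs[big, , drop = FALSE],
                                         expd[big, , drop = FALSE])
  }
  for (i in which(!big)) {
    tab <- rbind(obs[i, ], re[i, ])
    keep <- colSums(tab) > 0L
    p <- tryCatch(stats::fisher.test(tab[, keep, drop = FALSE])$p.value,
                  error = function(e) pearson_p_2x3(
                    obs[i, , drop = FALSE], expd[i, , drop = FALSE]))
    w$p_value[idx[i]] <- p
  }
  w[]
}

#' Tribe-wise permutation thresholds
#'
#' Permutes, within each species, the observed class labels over the fixed
#' site positions, re-runs the window pipeline, and records the largest
#' absolute per-species-normalised XY-ZW difference and the smallest
#' XY/ZW-window p-value across permutations.  Permutation p-values use the
#' chi-squared branch of the window test.
#'
#' @param sct a `site_class_table`.
#' @param n_perm number of permutations (study design: 100).
#' @param window,step as in [window_stats()].
#' @param seed integer seed.
#' @return list of class `tribe_thresholds`: `max_abs_diff_norm`,
#'   `min_perm_p`, `p_retention_cutoff` (1e-20), `n_perm`.
#' @export
permutation_thresholds <- function(sct, n_perm = 100L, window = 10000L,
                                   step = 2000L, seed = 1) {
  if (n_perm <= 0L) stop("n_perm must be positive")
  set.seed(seed)
  n_sp <- length(sct$species)
  max_diff <- -Inf
  min_p <- Inf
  for (b in seq_len(n_perm)) {
    cls_b <- apply(sct$cls, 2L, sample)
    w <- window_stats_from_counts(sct$sites, site_counts(cls_b), n_sp,
                                  window, step)
    w <- designate_windows(w)
    max_diff <- max(max_diff, abs(w$xy_zw_diff_norm))
    idx <- which(w$designation %in% c("XY", "ZW"))
    if (length(idx) > 0L) {
      p <- pearson_p_2x3(as.matrix(w[idx, .(obs_xy, obs_zw, obs_nosex)]),
                         as.matrix(w[idx, .(exp_xy, exp_zw, exp_nosex)]))
      min_p <- min(min_p, p)
    }
  }
  structure(list(max_abs_diff_norm = max_diff, min_perm_p = min_p,
                 p_retention_cutoff = 1e-20, n_perm = n_perm),
            class = "tribe_thresholds")
}

#' Default repeat-region masks of the reference genome
#'
#' A protocadherin tandem-array region on LG02 (21.36-21.93 Mb) and the
#' whole of LG03 (poor assembly quality) are masked from sex-chromosome
#' calls by default.
#'
#' @return data.frame with columns `lg_id`, `start`, `end`.
#' @export
default_region_masks <- function() {
  data.frame(lg_id = c("LG02", "LG03"),
             start = c(21360000, 1),
             end = c(21930000, Inf))
}

#' Call drastic XY/ZW outlier regions
#'
#' Retains windows whose designation is XY or ZW, whose normalised XY-ZW
#' difference exceeds the tribe-wise permutation threshold, and whose
#' -log10(p) exceeds 20; removes windows overlapping masked regions; merges
#' overlapping retained windows into regions (direction from the minimum-p
#' window, ties broken toward larger |XY-ZW difference|).
#'
#' @param w tested window table from [test_windows()].
#' @param th `tribe_thresholds`.
#' @param masks data.frame of regions to exclude
#'   (default [default_region_masks()]).
#' @return data.frame of outlier regions: `lg_id`, `start`, `end`,
#'   `direction`, `peak_neglog10_p`, `n_windows`.
#' @export
call_outlier_regions <- function(w, th, masks = default_region_masks()) {
  keep <- w$designation %in% c("XY", "ZW") &
    abs(w$xy_zw_diff_norm) > th$max_abs_diff_norm &
    !is.na(w$p_value) & w$p_value < th$p_retention_cutoff
  if (!is.null(masks) && nrow(masks) > 0L) {
    for (i in seq_len(nrow(masks))) {
      hit <- w$lg_id == masks$lg_id[i] & w$start <= masks$end[i] &
        w$end >= masks$start[i]
      keep <- keep & !hit
    }
  }
  ww <- w[keep]
  if (nrow(ww) == 0L)
    return(data.frame(lg_id = character(), start = integer(),
                      end = integer(), direction = character(),
                      peak_neglog10_p = numeric(), n_windows = integer()))
  data.table::setorder(ww, lg_id, start)
  ww[, grp := cumsum(c(1L, as.integer(
    lg_id[-1] != lg_id[-.N] | start[-1] > end[-.N] + 1L)))]
  regions <- ww[, {
    o <- order(p_value, -abs(xy_zw_diff))
    .(start = min(start), end = max(end),
      direction = designation[o[1L]],
      peak_neglog10_p = -log10(p_value[o[1L]]),
      n_windows = .N)
  }, by = .(lg_id, grp)]
  regions[, grp := NULL]
  as.data.frame(regions)
}

#' Attribute outlier regions to species
#'
#' For each region, individual genotypes over the region's sites are
#' clustered (Gower distance + divisive clustering); a species is assigned
#' the region's call when its male/female pair separates at the two-cluster
#' cut and its within-region XY-ZW difference matches the region direction.
#' A call is emitted only when at least two species of a tribe share it.
#'
#' @param regions regions from [call_outlier_regions()].
#' @param vt the `variant_table` the classification was computed from.
#' @param sct the matching `site_class_table`.
#' @param min_sites minimum region sites needed to attempt attribution.
#' @return data.frame of species calls: `species_id`, `tribe_id`, `lg_id`,
#'   `system`, `region_start`, `region_end`, `evidence` (`"A2"`), plus a
#'   `flag` column (`"insufficient sites"` when a region was skipped).
#' @export
attribute_species <- function(regions, vt, sct, min_sites = 10L) {
  panel <- sct$panel
  out <- list()
  g <- genotype_codes(vt)
  for (r in seq_len(nrow(regions))) {
    in_region <- vt$sites$lg_id == regions$lg_id[r] &
      vt$sites$pos >= regions$start[r] & vt$sites$pos <= regions$end[r]
    if (sum(in_region) < min_sites) {
      out[[length(out) + 1L]] <- data.frame(
        species_id = NA_character_, tribe_id = NA_character_,
        lg_id = regions$lg_id[r], system = regions$direction[r],
        region_start = regions$start[r], region_end = regions$end[r],
        evidence = "A2", flag = "insufficient sites")
      next
    }
    gm <- t(g[in_region, , drop = FALSE])
    cl <- divisive_two_cut(gower_genotype_dist(gm))
    sct_idx <- sct$sites$lg_id == regions$lg_id[r] &
      sct$sites$pos >= regions$start[r] & sct$sites$pos <= regions$end[r]
    dir_sign <- if (regions$direction[r] == "XY") 1L else -1L
    hits <- character(0)
    tribes <- character(0)
    for (sp in sct$species) {
      p <- panel[panel$species_id == sp, ]
      male <- p$individual_id[p$sex == "male"][1L]
      female <- p$individual_id[p$sex == "female"][1L]
      ci <- sct$cls[sct_idx, sp]
      diff_sp <- sum(ci == 1L) - sum(ci == 2L)
      if (pair_separates(cl, male, female) && sign(diff_sp) == dir_sign) {
        hits <- c(hits, sp)
        tribes <- c(tribes, p$tribe_id[1L])
      }
    }
    shared <- table(tribes)
    keep <- tribes %in% names(shared)[shared >= 2L]
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        species_id = hits[keep], tribe_id = tribes[keep],
        lg_id = regions$lg_id[r], system = regions$direction[r],
        region_start = regions$start[r], region_end = regions$end[r],
        evidence = "A2", flag = NA_character_)
  }
  if (length(out) == 0L)
    return(data.frame(species_id = character(), tribe_id = character(),
                      lg_id = character(), system = character(),
                      region_start = integer(), region_end = integer(),
                      evidence = character(), flag = character()))
  do.call(rbind, out)
}

#' Run the full WGS accumulation scan for one tribe
#'
#' Convenience wrapper: classify sites, window statistics, window tests,
#' permutation thresholds, outlier regions, species attribution.
#'
#' @param vt filtered `variant_table` of the tribe's individuals.
#' @param panel matching `sample_panel`.
#' @param n_perm permutations for the threshold (study design: 100).
#' @param method window test, see [test_windows()].
#' @param masks region masks, see [call_outlier_regions()].
#' @param seed integer seed.
#' @return list with `windows`, `thresholds`, `regions`, `calls`.
#' @export
scan_wgs <- function(vt, panel, n_perm = 100L, method = "fisher",
                     masks = default_region_masks(), seed = 1) {
  sct <- classify_sites(vt, panel)
  w <- test_windows(window_stats(sct), method = method)
  th <- permutation_thresholds(sct, n_perm = n_perm, seed = seed)
  regions <- call_outlier_regions(w, th, masks = masks)
  calls <- attribute_species(regions, vt, sct)
  list(windows = w, thresholds = th, regions = regions, calls = calls,
       site_classes = sct)
}
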