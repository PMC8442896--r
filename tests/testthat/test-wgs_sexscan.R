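test_that("site classification follows the male/female genotype rules", {
  panel <- make_panel(1)
  #              male f
  g <- rbind(c(1L, 0L),   # male het, female hom_ref -> XY
             c(1L, 2L),   # male het, female hom_alt -> XY
             c(2L, 1L),   # female het, male hom_alt -> ZW
             c(1L, 1L),   # same genotype -> nosex
             c(0L, 2L),   # opposite homozygotes -> nosex
             c(NA, 1L),   # male missing -> noinfo
             c(0L, 0L))   # same genotype -> nosex
  vt <- vt_from_codes(g, panel)
  sct <- classify_sites(vt, panel)
  expect_equal(unname(sct$cls[, "sp1"]), c(1L, 1L, 2L, 3L, 3L, 4L, 3L))
  expect_equal(attr(sct, "n_opposite_hom"), 1L)
  # conservation: classes sum to number of sites for each species
  cc <- class_counts(sct)
  expect_true(all(rowSums(cc) == n_sites(vt)))
  # a species lacking one sex is skipped with a warning
  panel2 <- sample_panel(data.frame(
    individual_id = c("a_m", "a_f", "b_m"),
    species_id = c("a", "a", "b"), tribe_id = "T1",
    sex = c("male", "female", "male")))
  vt2 <- vt_from_codes(g[, c(1, 2, 1)], panel2)
  expect_warning(sct2 <- classify_sites(vt2, panel2), "b")
  expect_equal(sct2$species, "a")
})

test_that("sliding windows cover each site the expected number of times", {
  panel <- make_panel(1)
  g <- matrix(c(1L, 0L), 1, 2)     # one XY site
  vt <- vt_from_codes(g, panel, pos = 10500L)
  sct <- classify_sites(vt, panel)
  w <- window_stats(sct)
  # 10-kb windows sliding by 2 kb that contain position 10,500:
  # starts 2001, 4001, 6001, 8001, 10001 -> exactly 5 windows
  expect_equal(nrow(w), 5L)
  expect_equal(w$start, c(2001L, 4001L, 6001L, 8001L, 10001L))
  expect_true(all(w$obs_xy == 1L))
})

test_that("expected counts are genome-wide fractions times called sites", {
  panel <- make_panel(2)
  lgs <- make_lgs(1, 300000L)
  sim <- simulate_wgs_cohort(panel, lgs, make_truth(2, 0), 1000, seed = 4)
  sct <- classify_sites(sim$vt, panel)
  w <- window_stats(sct)
  tot <- colSums(sexchromevol:::site_counts(sct$cls))
  frac_xy <- tot[["xy"]] / sum(tot)
  expect_equal(w$exp_xy, frac_xy * w$n_called, tolerance = 1e-12)
  expect_equal(w$xy_zw_diff, w$obs_xy - w$obs_zw)
  expect_equal(w$xy_zw_diff_norm, w$xy_zw_diff / 2)
})

test_that("window designation and exact test match the enumeration oracle", {
  w <- data.table::data.table(
    lg_id = "LG05", start = c(1L, 1L, 1L, 1L), end = 10000L,
    obs_xy = c(30L, 10L, 3L, 3L), obs_zw = c(1L, 10L, 3L, 3L),
    obs_nosex = c(269L, 280L, 294L, 294L),
    exp_xy = c(3, 3, 3, 4), exp_zw = c(3, 3, 3, 2),
    exp_nosex = c(294, 294, 294, 294))
  w$n_called <- w$obs_xy + w$obs_zw + w$obs_nosex
  w$xy_zw_diff <- w$obs_xy - w$obs_zw
  w$xy_zw_diff_norm <- w$xy_zw_diff / 5
  out <- test_windows(w, method = "fisher")
  expect_equal(out$designation, c("XY", "ambiguous", "nosex", "ZW"))
  expect_true(is.na(out$p_value[2L]))       # ambiguous: no p reported
  expect_true(is.na(out$p_value[3L]))
  # oracle agreement on the XY window's rounded 2x3 table
  tab <- rbind(c(30L, 1L, 269L), c(3L, 3L, 294L))
  expect_equal(out$p_value[1L], oracle_fisher_2x3(tab), tolerance = 1e-9)
})

test_that("exact p matches hypergeometric enumeration on small tables", {
  set.seed(42)
  for (i in 1:8) {
    tab <- matrix(rpois(6, 6) + 1L, 2, 3)
    expect_equal(stats::fisher.test(tab)$p.value, oracle_fisher_2x3(tab),
                 tolerance = 1e-9)
  }
})

test_that("permutations preserve class totals and need n_perm > 0", {
  panel <- make_panel(2)
  lgs <- make_lgs(1, 200000L)
  sim <- simulate_wgs_cohort(panel, lgs, make_truth(2, 1,
                             region = c(50001L, 150000L)), 400, seed = 2)
  sct <- classify_sites(sim$vt, panel)
  expect_error(permutation_thresholds(sct, n_perm = 0), "positive")
  set.seed(1)
  cls_b <- apply(sct$cls, 2L, sample)
  expect_equal(apply(cls_b, 2L, tabulate, nbins = 4L),
               apply(sct$cls, 2L, tabulate, nbins = 4L))
  th <- permutation_thresholds(sct, n_perm = 10, seed = 3)
  expect_gt(th$max_abs_diff_norm, 0)
  expect_equal(th$p_retention_cutoff, 1e-20)
})

test_that("outlier region calling applies thresholds, masks and merging", {
  th <- structure(list(max_abs_diff_norm = 2, min_perm_p = 1e-6,
                       p_retention_cutoff = 1e-20, n_perm = 100L),
                  class = "tribe_thresholds")
  w <- data.table::data.table(
    lg_id = c("LG05", "LG05", "LG05", "LG02", "LG03"),
    start = c(1L, 2001L, 40001L, 21400001L, 1L),
    end = c(10000L, 12000L, 50000L, 21410000L, 10000L),
    obs_xy = 50L, obs_zw = 0L, obs_nosex = 100L,
    exp_xy = 5, exp_zw = 5, exp_nosex = 140,
    n_called = 150L, xy_zw_diff = 50L, xy_zw_diff_norm = 10,
    designation = "XY",
    p_value = c(1e-30, 1e-35, 10^-19.5, 1e-30, 1e-30))
  regions <- call_outlier_regions(w, th)
  # window 3 fails -log10(p) > 20; LG02 window masked; LG03 masked;
  # windows 1 and 2 overlap -> one merged region
  expect_equal(nrow(regions), 1L)
  expect_equal(regions$start, 1L)
  expect_equal(regions$end, 12000L)
  expect_equal(regions$direction, "XY")
  expect_equal(regions$peak_neglog10_p, 35)
})

test_that("species attribution clusters pairs by sex and needs two sharers", {
  panel <- make_panel(4)
  lgs <- make_lgs(1, 400000L)
  # two species share the planted XY system, two are background
  truth <- make_truth(4, 2, region = c(100001L, 300000L))
  sim <- simulate_wgs_cohort(panel, lgs, truth, 1200, seed = 6)
  sct <- classify_sites(sim$vt, panel)
  regions <- data.frame(lg_id = "LG05", start = 100001L, end = 300000L,
                        direction = "XY", peak_neglog10_p = 50,
                        n_windows = 10L)
  calls <- attribute_species(regions, sim$vt, sct)
  expect_setequal(calls$species_id, c("sp1", "sp2"))
  expect_true(all(calls$system == "XY"))
  # identical genotype vectors have Gower distance zero
  m <- rbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L))
  expect_equal(as.numeric(gower_genotype_dist(m)), 0)
  # a single sharer yields no call: restrict the panel to one carrier
  panel1 <- make_panel(3)
  truth1 <- make_truth(3, 1, region = c(100001L, 300000L))
  sim1 <- simulate_wgs_cohort(panel1, lgs, truth1, 1200, seed = 6)
  sct1 <- classify_sites(sim1$vt, panel1)
  calls1 <- attribute_species(regions, sim1$vt, sct1)
  expect_equal(nrow(calls1[is.na(calls1$flag), ]), 0L)
  # regions with too few sites are flagged
  tiny <- data.frame(lg_id = "LG05", start = 1L, end = 400L,
                     direction = "XY", peak_neglog10_p = 50, n_windows = 1L)
  out <- attribute_species(tiny, sim$vt, sct)
  expect_true(all(out$flag == "insufficient sites"))
})

test_that("the scan recovers planted systems and stays quiet on null data", {
  panel <- make_panel(6)
  lgs <- make_lgs(2, 800000L)
  truth <- make_truth(6, 4, system = "XY", region = c(200001L, 500000L))
  null_truth <- make_truth(6, 0)
  hits <- 0L
  fp <- 0L
  n_seeds <- 8L
  for (s in seq_len(n_seeds)) {
    sim <- simulate_wgs_cohort(panel, lgs, truth, 4000,
                               missing_frac = 0.02, seed = s)
    vt <- apply_genotype_filters(mask_around_indels(sim$vt))
    res <- scan_wgs(vt, panel, n_perm = 100, seed = s, masks = NULL)
    called <- unique(res$calls$species_id[res$calls$system == "XY" &
                                            res$calls$lg_id == "LG05"])
    if (setequal(called, paste0("sp", 1:4))) hits <- hits + 1L
    sim0 <- simulate_wgs_cohort(panel, lgs, null_truth, 4000,
                                missing_frac = 0.02, seed = s + 100L)
    vt0 <- apply_genotype_filters(mask_around_indels(sim0$vt))
    res0 <- scan_wgs(vt0, panel, n_perm = 100, seed = s, masks = NULL)
    if (nrow(res0$calls[is.na(res0$calls$flag), ]) > 0L) fp <- fp + 1L
  }
  expect_equal(hits, n_seeds)     # 100% recall at d = 1
  expect_lte(fp, ceiling(0.05 * n_seeds))
})

test_that("the wgs scan is deterministic under a fixed seed", {
  panel <- make_panel(3)
  lgs <- make_lgs(1, 300000L)
  truth <- make_truth(3, 2, region = c(50001L, 250000L))
  sim <- simulate_wgs_cohort(panel, lgs, truth, 800, seed = 5)
  r1 <- scan_wgs(sim$vt, panel, n_perm = 20, seed = 11, masks = NULL)
  r2 <- scan_wgs(sim$vt, panel, n_perm = 20, seed = 11, masks = NULL)
  expect_identical(r1$thresholds, r2$thresholds)
  expect_identical(r1$calls, r2$calls)
})
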