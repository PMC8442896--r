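# Approach 3: species-level sex-linkage detection from replicate
# transcriptome allele counts.  Sex-differential SNPs are screened by a
# pooled exact test with Benjamini-Hochberg adjustment, classified by
# sex-exclusive expression, aggregated in 10-kb windows, and the
# heterogametic system and candidate LG(s) are decided from window
# outliers.

#' Construct an allele-count table
#'
#' @param snps data.frame with columns `lg_id`, `pos`.
#' @param ref,alt numeric matrices of read counts, SNPs x replicates.
#' @param sex character vector, one of `"male"`/`"female"` per replicate.
#' @param replicate_id replicate names.
#' @return object of class `allele_count_table`.
#' @export
allele_count_table <- function(snps, ref, alt, sex, replicate_id = NULL) {
  snps <- as.data.frame(snps)
  if (is.null(replicate_id))
    replicate_id <- paste0(sex, stats::ave(seq_along(sex), sex,
                                           FUN = seq_along))
  stopifnot(nrow(ref) == nrow(snps), nrow(alt) == nrow(snps),
            ncol(ref) == length(sex), ncol(alt) == length(sex),
            all(sex %in% c("male", "female")),
            all(ref >= 0), all(alt >= 0))
  colnames(ref) <- colnames(alt) <- replicate_id
  structure(list(snps = snps, ref = ref, alt = alt, sex = sex,
                 replicate_id = replicate_id),
            class = "allele_count_table")
}

subset_act <- function(act, keep) {
  act$snps <- act$snps[keep, , drop = FALSE]
  act$ref <- act$ref[keep, , drop = FALSE]
  act$alt <- act$alt[keep, , drop = FALSE]
  if (!is.null(act$snps$adj_p)) act$snps$adj_p <- act$snps$adj_p[]
  act
}

#' Read an allele-count table from TSV
#'
#' Expected columns: `lg_id`, `pos`, then `<sex><idx>_ref` / `<sex><idx>_alt`
#' pairs (e.g. `male1_ref`, `male1_alt`, ..., `female3_alt`).
#'
#' @param path TSV file.
#' @return an `allele_count_table`.
#' @export
read_allele_counts <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  rc <- grep("_ref$", names(x), value = TRUE)
  ac <- sub("_ref$", "_alt", rc)
  if (!all(ac %in% names(x))) stop("unpaired _ref/_alt columns")
  reps <- sub("_ref$", "", rc)
  sex <- ifelse(grepl("^male", reps), "male", "female")
  allele_count_table(x[, c("lg_id", "pos")],
                     as.matrix(x[, rc]), as.matrix(x[, ac]), sex, reps)
}

#' Write an allele-count table as TSV
#' @param act an `allele_count_table`.
#' @param path output file.
#' @export
write_allele_counts <- function(act, path) {
  out <- act$snps[, c("lg_id", "pos")]
  for (j in seq_along(act$replicate_id)) {
    out[[paste0(act$replicate_id[j], "_ref")]] <- act$ref[, j]
    out[[paste0(act$replicate_id[j], "_alt")]] <- act$alt[, j]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Filter SNPs for sex-differential allele use
#'
#' Per SNP, ref/alt counts pooled by sex are compared with a two-sided
#' Fisher exact test; p-values are Benjamini-Hochberg adjusted and SNPs
#' with adjusted p <= `alpha` are retained.  SNPs on mitochondrial or
#' unplaced sequence are removed first.
#'
#' @param act an `allele_count_table` (>= 2 replicates per sex).
#' @param alpha adjusted-p cutoff.
#' @param drop_lgs LG ids removed before testing.
#' @return the filtered `allele_count_table`; `snps$adj_p` holds the
#'   adjusted p-values.
#' @export
filter_sex_biased_snps <- function(act, alpha = 0.05,
                                   drop_lgs = c("MT", "UNPLACED")) {
  stopifnot(sum(act$sex == "male") >= 2L, sum(act$sex == "female") >= 2L)
  act <- subset_act(act, !(act$snps$lg_id %in% drop_lgs))
  n <- nrow(act$snps)
  if (n == 0L) {
    act$snps$adj_p <- numeric(0)
    return(act)
  }
  m <- act$sex == "male"
  p <- vapply(seq_len(n), function(i) {
    # replicates with zero total counts carry no information at this SNP
    use <- (act$ref[i, ] + act$alt[i, ]) > 0
    tab <- rbind(c(sum(act$ref[i, use & m]), sum(act$alt[i, use & m])),
                 c(sum(act$ref[i, use & !m]), sum(act$alt[i, use & !m])))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    stats::fisher.test(tab)$p.value
  }, 1.0)
  act$snps$adj_p <- stats::p.adjust(p, method = "BH")
  subset_act(act, act$snps$adj_p <= alpha)
}

#' Classify SNPs as XY / ZW by sex-exclusive expression
#'
#' A SNP's alternative allele is XY when it has zero read counts in all
#' females and at least one count in at least two males; ZW mirrored.
#'
#' @param act a filtered `allele_count_table`.
#' @return the table with `snps$class` in `{"XY", "ZW", NA}`.
#' @export
classify_rna_snps <- function(act) {
  m <- act$sex == "male"
  alt_m <- act$alt[, m, drop = FALSE]
  alt_f <- act$alt[, !m, drop = FALSE]
  xy <- rowSums(alt_f) == 0 & rowSums(alt_m >= 1) >= 2L
  zw <- rowSums(alt_m) == 0 & rowSums(alt_f >= 1) >= 2L
  act$snps$class <- ifelse(xy, "XY", ifelse(zw, "ZW", NA_character_))
  act
}

#' XY-ZW differences in 10-kb windows and outlier flags
#'
#' Counts classified SNPs in non-overlapping 10-kb windows (windows with at
#' least one classified SNP enter the genome-wide distribution).  A window
#' is an outlier when its XY-ZW difference exceeds Q3 + 1.5 IQR of the
#' genome-wide differences; with `one_sided = FALSE` (default) the mirrored
#' low tail (below Q1 - 1.5 IQR) flags ZW-dominated outliers too.
#'
#' @param act a classified `allele_count_table`.
#' @param window window width, bp.
#' @param one_sided restrict to the literal high-tail rule.
#' @return data.frame per window: `lg_id`, `start`, `end`, `n_xy`, `n_zw`,
#'   `diff`, `outlier`.
#' @export
rna_outlier_windows <- function(act, window = 10000L, one_sided = FALSE) {
  cls <- act$snps$class
  keep <- !is.na(cls)
  if (!any(keep)) stop("no classified SNPs")
  dt <- data.table::data.table(
    lg_id = act$snps$lg_id[keep],
    start = (act$snps$pos[keep] - 1L) %/% window * window + 1L,
    class = cls[keep])
  w <- dt[, .(n_xy = sum(class == "XY"), n_zw = sum(class == "ZW")),
          by = .(lg_id, start)]
  w[, end := start + window - 1L]
  w[, diff := n_xy - n_zw]
  q <- stats::quantile(w$diff, c(0.25, 0.75), type = 7)
  iqr <- q[2] - q[1]
  hi <- q[2] + 1.5 * iqr
  lo <- q[1] - 1.5 * iqr
  w[, outlier := diff > hi | (!one_sided & diff < lo)]
  data.table::setorder(w, lg_id, start)
  as.data.frame(w[, .(lg_id, start, end, n_xy, n_zw, diff, outlier)])
}

#' Decide the heterogametic system from outlier windows
#'
#' Paired two-sided Wilcoxon signed-rank comparison of XY and ZW SNP counts
#' across outlier windows; when p < 0.05 the system is the side with the
#' larger total SNP count, otherwise none.
#'
#' @param rwt window table from [rna_outlier_windows()].
#' @param min_windows minimum number of outlier windows to attempt a call.
#' @return list: `system` (`"XY"`, `"ZW"` or `"none"`), `p_value`, `reason`.
#' @export
decide_heterogamety <- function(rwt, min_windows = 3L) {
  ow <- rwt[rwt$outlier, , drop = FALSE]
  if (nrow(ow) < min_windows)
    return(list(system = "none", p_value = NA_real_,
                reason = sprintf("only %d outlier window(s)", nrow(ow))))
  if (all(ow$n_xy == ow$n_zw))
    return(list(system = "none", p_value = 1, reason = "no difference"))
  p <- suppressWarnings(
    stats::wilcox.test(ow$n_xy, ow$n_zw, paired = TRUE,
                       alternative = "two.sided")$p.value)
  if (is.na(p) || p >= 0.05)
    return(list(system = "none", p_value = p, reason = "not significant"))
  system <- if (sum(ow$n_xy) > sum(ow$n_zw)) "XY" else "ZW"
  list(system = system, p_value = p, reason = "significant")
}

#' Call candidate sex-linked LG(s)
#'
#' Counts system-matching SNPs of outlier windows per LG, normalised by LG
#' length (SNPs per Mb); candidates must exceed Q3 + 3 IQR of the per-LG
#' normalised counts and, to keep only the most extreme outliers, also
#' exceed mean + 1 SD (`sd_mode = "mean_plus_sd"`; `"literal"` compares the
#' count to the SD itself).
#'
#' @param act classified `allele_count_table`.
#' @param rwt window table from [rna_outlier_windows()].
#' @param system decided heterogametic system (`"XY"` or `"ZW"`).
#' @param lgs an `lg_table`.
#' @param sd_mode see above.
#' @return list: `candidate_lgs` (possibly `"unassigned"`), `per_lg`
#'   (data.frame of normalised counts).
#' @export
call_candidate_lgs <- function(act, rwt, system, lgs,
                               sd_mode = c("mean_plus_sd", "literal")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(system %in% c("XY", "ZW"))
  ow <- rwt[rwt$outlier, , drop = FALSE]
  in_outlier <- rep(FALSE, nrow(act$snps))
  for (i in seq_len(nrow(ow)))
    in_outlier <- in_outlier | (act$snps$lg_id == ow$lg_id[i] &
                                  act$snps$pos >= ow$start[i] &
                                  act$snps$pos <= ow$end[i])
  hit <- in_outlier & !is.na(act$snps$class) & act$snps$class == system
  counts <- table(factor(act$snps$lg_id[hit], levels = lgs$lg_id))
  norm <- as.numeric(counts) / (lgs$length_bp / 1e6)
  q <- stats::quantile(norm, c(0.25, 0.75), type = 7)
  thr_iqr <- q[2] + 3 * (q[2] - q[1])
  thr_sd <- if (sd_mode == "mean_plus_sd")
    mean(norm) + stats::sd(norm) else stats::sd(norm)
  cand <- lgs$lg_id[norm > thr_iqr & norm > thr_sd]
  per_lg <- data.frame(lg_id = lgs$lg_id, n_snps = as.integer(counts),
                       snps_per_mb = norm)
  list(candidate_lgs = if (length(cand) == 0L) "unassigned" else cand,
       per_lg = per_lg)
}

#' Run the full transcriptome scan for one species
#'
#' @param act raw `allele_count_table`.
#' @param lgs an `lg_table`.
#' @param species_id reported in the call.
#' @param alpha BH-adjusted p cutoff for the SNP filter.
#' @return list with `system`, `p_value`, `candidate_lgs`, `windows`,
#'   `per_lg`, and the species' call row (`calls`, empty when no system).
#' @export
scan_rna <- function(act, lgs, species_id = "species", alpha = 0.05) {
  act <- classify_rna_snps(filter_sex_biased_snps(act, alpha = alpha))
  empty <- data.frame(species_id = character(), lg_id = character(),
                      system = character(), evidence = character())
  if (!any(!is.na(act$snps$class)))
    return(list(system = "none", p_value = NA_real_,
                candidate_lgs = character(), windows = NULL, per_lg = NULL,
                calls = empty))
  rwt <- rna_outlier_windows(act)
  dec <- decide_heterogamety(rwt)
  if (dec$system == "none")
    return(list(system = "none", p_value = dec$p_value,
                candidate_lgs = character(), windows = rwt, per_lg = NULL,
                calls = empty))
  lg <- call_candidate_lgs(act, rwt, dec$system, lgs)
  calls <- data.frame(species_id = species_id,
                      lg_id = lg$candidate_lgs,
                      system = dec$system, evidence = "A3")
  list(system = dec$system, p_value = dec$p_value,
       candidate_lgs = lg$candidate_lgs, windows = rwt,
       per_lg = lg$per_lg, calls = calls)
}
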