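# Sizing of sex-differentiated regions, their relation to sex-chromosome
# age, and X/Y haplotype extraction for convergence testing.

#' Size the sex-differentiated region of a called species
#'
#' Counts system-matching sex-specific SNPs per 10-kb non-overlapping
#' window on the called LG(s); windows whose count exceeds twice the
#' genome-wide mean (over all windows of all LGs) qualify.  The cumulative
#' length of qualifying windows, their coordinate range, and the
#' proportion of the LG they cover are returned.
#'
#' @param sct a `site_class_table`.
#' @param species_id the called species.
#' @param call_lgs character vector of called LG(s).
#' @param system `"XY"` or `"ZW"`.
#' @param lgs an `lg_table`.
#' @param window window width, bp.
#' @return data.frame, one row per called LG: `species_id`, `lg_id`,
#'   `cumulative_bp`, `range_start`, `range_end`, `proportion_of_lg`.
#' @export
differentiation_regions <- function(sct, species_id, call_lgs, system,
                                    lgs, window = 10000L) {
  stopifnot(system %in% c("XY", "ZW"), species_id %in% sct$species)
  code <- if (system == "XY") 1L else 2L
  hit <- sct$cls[, species_id] == code
  # genome-wide mean density over ALL windows (window grid per LG length)
  win_of <- (sct$sites$pos - 1L) %/% window
  counts <- table(paste(sct$sites$lg_id, win_of)[hit])
  n_windows_total <- sum(ceiling(lgs$length_bp / window))
  gw_mean <- sum(hit) / n_windows_total
  thr <- 2 * gw_mean
  out <- lapply(call_lgs, function(lg) {
    len <- lgs$length_bp[lgs$lg_id == lg]
    if (length(len) != 1L)
      return(data.frame(species_id = species_id, lg_id = lg,
                        cumulative_bp = 0L, range_start = NA_integer_,
                        range_end = NA_integer_, proportion_of_lg = 0))
    on_lg <- sct$sites$lg_id == lg & hit
    wc <- table((sct$sites$pos[on_lg] - 1L) %/% window)
    qual <- as.integer(names(wc)[as.numeric(wc) > thr])
    if (gw_mean == 0 || length(qual) == 0L)
      return(data.frame(species_id = species_id, lg_id = lg,
                        cumulative_bp = 0L, range_start = NA_integer_,
                        range_end = NA_integer_, proportion_of_lg = 0))
    starts <- qual * window + 1L
    ends <- pmin(starts + window - 1L, len)
    cum <- sum(ends - starts + 1L)
    data.frame(species_id = species_id, lg_id = lg,
               cumulative_bp = cum, range_start = min(starts),
               range_end = max(ends),
               proportion_of_lg = cum / len)
  })
  do.call(rbind, out)
}

#' pGLS of sex-chromosome differentiation against system age
#'
#' @param proportions named numeric vector: per species, the proportion of
#'   the called LG covered by sex-differentiated windows.
#' @param ages named numeric vector: per species, the estimated age (My)
#'   of its sex-chromosome system (time of the turnover event).
#' @param tree time tree over (at least) these species.
#' @return a `pgls_fit` of `proportion ~ age`.
#' @export
age_differentiation_pgls <- function(proportions, ages, tree) {
  pgls_fit(proportions, ages, tree)
}

#' Extract X and Y haplotypes at sex-linked sites
#'
#' Restricts to sites that are XY-classified in at least one focal species
#' and have less than `max_missing` missing data across the included
#' individuals.  For each focal male at its XY sites (male heterozygous,
#' female homozygous), the allele shared with the female is the X
#' haplotype, the other the Y.  Other individuals contribute both unphased
#' alleles in arbitrary (seed-randomised) order.  Missing alleles become
#' `N`.
#'
#' @param vt a filtered `variant_table`.
#' @param sct matching `site_class_table`.
#' @param focal_species species with the shared XY system.
#' @param include_individuals additional individual ids to include
#'   (default: all panel individuals).
#' @param max_missing maximum tolerated missing fraction per site.
#' @param seed seed for the arbitrary ordering of non-focal haplotypes.
#' @return list: `haplotypes` (character matrix, one row per haplotype,
#'   rownames `<individual>_<X|Y|h1|h2>`), `sites` (the retained site
#'   table).  Focal species with no XY site are dropped with a warning.
#' @export
extract_sex_haplotypes <- function(vt, sct, focal_species,
                                   include_individuals = NULL,
                                   max_missing = 0.10, seed = 1) {
  set.seed(seed)
  panel <- sct$panel
  if (is.null(include_individuals))
    include_individuals <- panel$individual_id
  focal_species <- focal_species[focal_species %in% sct$species]
  has_xy <- vapply(focal_species, function(sp)
    any(sct$cls[, sp] == 1L), TRUE)
  if (any(!has_xy)) {
    warning("focal species without XY sites excluded: ",
            paste(focal_species[!has_xy], collapse = ", "))
    focal_species <- focal_species[has_xy]
  }
  if (length(focal_species) == 0L) stop("no focal species with XY sites")
  xy_any <- rowSums(sct$cls[, focal_species, drop = FALSE] == 1L) > 0L
  gsub_idx <- match(include_individuals, colnames(vt$a1))
  miss <- rowMeans(is.na(vt$a1[, gsub_idx, drop = FALSE]))
  keep <- which(xy_any & miss < max_missing)
  if (length(keep) == 0L) stop("no sites pass the filters")
  alleles <- cbind(vt$sites$ref, vt$sites$alt)[keep, , drop = FALSE]
  allele_char <- function(site_row, idx)
    ifelse(is.na(idx), "N", ifelse(idx == 0L, alleles[site_row, 1L],
                                   alleles[site_row, 2L]))
  haps <- list()
  for (ind in include_individuals) {
    sp <- panel$species_id[panel$individual_id == ind]
    sex <- panel$sex[panel$individual_id == ind]
    a1 <- vt$a1[keep, ind]
    a2 <- vt$a2[keep, ind]
    rows <- seq_along(keep)
    if (sp %in% focal_species && sex == "male") {
      female <- panel$individual_id[panel$species_id == sp &
                                      panel$sex == "female"][1L]
      f1 <- vt$a1[keep, female]
      # X carries the allele shared with the homozygous female
      is_xy <- sct$cls[keep, sp] == 1L & !is.na(a1) & !is.na(a2) &
        a1 != a2 & !is.na(f1)
      x_al <- ifelse(is_xy, ifelse(a1 == f1, a1, a2), a1)
      y_al <- ifelse(is_xy, ifelse(a1 == f1, a2, a1), a2)
      haps[[paste0(ind, "_X")]] <- allele_char(rows, x_al)
      haps[[paste0(ind, "_Y")]] <- allele_char(rows, y_al)
    } else {
      swap <- sample(c(TRUE, FALSE), 1L)
      h1 <- if (swap) a2 else a1
      h2 <- if (swap) a1 else a2
      haps[[paste0(ind, "_h1")]] <- allele_char(rows, h1)
      haps[[paste0(ind, "_h2")]] <- allele_char(rows, h2)
    }
  }
  list(haplotypes = do.call(rbind, haps),
       sites = vt$sites[keep, c("lg_id", "pos")])
}

#' Write haplotypes to FASTA
#' @param haps character matrix from [extract_sex_haplotypes()].
#' @param path output file.
#' @export
write_haplotype_fasta <- function(haps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(haps))) {
    writeLines(paste0(">", rownames(haps)[i]), con)
    writeLines(paste(haps[i, ], collapse = ""), con)
  }
}

#' Neighbor-joining tree of haplotype sequences
#'
#' Pairwise Hamming distances (mismatch fraction over sites where neither
#' sequence is `N`), neighbor-joining, negative branch lengths clamped to
#' zero.
#'
#' @param haps character matrix (haplotypes x sites) or path to a FASTA
#'   file of equal-length sequences.
#' @return an `ape::phylo`.
#' @export
haplotype_nj_tree <- function(haps) {
  if (is.character(haps) && length(haps) == 1L) {
    seqs <- ape::read.FASTA(haps)
    lens <- lengths(seqs)
    if (length(unique(lens)) != 1L) stop("sequences have unequal lengths")
    haps <- toupper(do.call(rbind, as.character(seqs)))
  }
  if (nrow(haps) < 3L) stop("need at least 3 sequences")
  n <- nrow(haps)
  d <- matrix(0, n, n, dimnames = list(rownames(haps), rownames(haps)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- haps[i, ] != "N" & haps[j, ] != "N"
      d[i, j] <- d[j, i] <-
        if (any(ok)) mean(haps[i, ok] != haps[j, ok]) else 0
    }
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
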