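#' @importFrom stats setNames
NULL

# ---------------------------------------------------------------------------
# Sample panels and linkage-group tables
# ---------------------------------------------------------------------------

#' Build or validate a sample panel
#'
#' A sample panel maps each sequenced individual to its species, tribe and
#' sex.  Downstream scans assume one male and one female genome per species
#' (extra individuals are tolerated; the designated pair is the first male
#' and first female listed for a species).
#'
#' @param x a data.frame with columns `individual_id`, `species_id`,
#'   `tribe_id`, `sex` (values `"male"`/`"female"`).
#' @return a validated `sample_panel` data.frame.
#' @export
sample_panel <- function(x) {
  need <- c("individual_id", "species_id", "tribe_id", "sex")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[, need]
  for (j in need) x[[j]] <- as.character(x[[j]])
  if (anyDuplicated(x$individual_id))
    stop("duplicate individual_id in panel")
  if (any(is.na(x$sex)) || !all(x$sex %in% c("male", "female")))
    stop("panel sex must be 'male' or 'female' and never missing")
  if (any(is.na(x$species_id)) || any(x$species_id == ""))
    stop("panel species_id must be non-missing")
  class(x) <- c("sample_panel", "data.frame")
  x
}

#' Read a sample panel from TSV
#'
#' @param path TSV file with header
#'   `individual_id  species_id  tribe_id  sex`.
#' @return a `sample_panel` data.frame.
#' @export
read_panel <- function(path) {
  sample_panel(utils::read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
}

#' Build or read a linkage-group length table
#'
#' @param x data.frame with columns `lg_id`, `length_bp`, or a path to a TSV
#'   with that header.
#' @return validated data.frame of class `lg_table`.
#' @export
lg_table <- function(x) {
  if (is.character(x) && length(x) == 1L)
    x <- utils::read.table(x, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("lg_id", "length_bp") %in% names(x)))
    stop("lg table needs columns lg_id, length_bp")
  x <- as.data.frame(x)[, c("lg_id", "length_bp")]
  x$lg_id <- as.character(x$lg_id)
  x$length_bp <- as.integer(x$length_bp)
  if (anyDuplicated(x$lg_id)) stop("duplicate lg_id")
  if (any(x$length_bp <= 0L)) stop("LG lengths must be positive")
  class(x) <- c("lg_table", "data.frame")
  x
}

# ---------------------------------------------------------------------------
# Variant tables
# ---------------------------------------------------------------------------

#' Construct a variant table
#'
#' The central WGS container: per-site metadata plus per-individual allele
#' calls and genotype quality/depth.  Allele calls are stored as two integer
#' matrices (`a1`, `a2`) of VCF allele indices (0 = reference), `NA` for
#' missing, so that multiallelic records survive until filtering.
#'
#' @param sites data.frame with columns `lg_id`, `pos`, `ref`, `alt`
#'   (comma-separated string of alternative alleles), `is_indel`,
#'   `indel_size`.
#' @param a1,a2 integer matrices, sites x individuals.
#' @param gq,dp numeric matrices, sites x individuals.
#' @param panel the `sample_panel` the columns refer to.
#' @return object of class `variant_table`.
#' @export
variant_table <- function(sites, a1, a2, gq, dp, panel) {
  sites <- as.data.frame(sites)
  n <- nrow(sites)
  ids <- panel$individual_id
  for (m in list(a1, a2, gq, dp)) {
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != length(ids))
      stop("genotype matrices must be sites x panel individuals")
  }
  if (any(sites$is_indel & (is.na(sites$indel_size) | sites$indel_size < 1)))
    stop("indel_size must be >= 1 for indel records")
  ord_ok <- all(tapply(sites$pos, sites$lg_id,
                       function(p) !is.unsorted(p, strictly = TRUE)))
  if (n > 0L && !ord_ok)
    stop("positions must be strictly increasing within each LG")
  colnames(a1) <- colnames(a2) <- colnames(gq) <- colnames(dp) <- ids
  structure(list(sites = sites, a1 = a1, a2 = a2, gq = gq, dp = dp,
                 panel = panel),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "sites x",
      nrow(x$panel), "individuals on",
      length(unique(x$sites$lg_id)), "LG(s)\n")
  invisible(x)
}

#' Number of sites in a variant table
#' @param vt a `variant_table`.
#' @export
n_sites <- function(vt) nrow(vt$sites)

#' Genotype codes of a variant table
#'
#' @param vt a `variant_table`.
#' @return integer matrix sites x individuals: 0 homozygous reference,
#'   1 heterozygous, 2 homozygous alternative, `NA` missing.
#' @export
genotype_codes <- function(vt) {
  g <- matrix(NA_integer_, nrow(vt$a1), ncol(vt$a1),
              dimnames = dimnames(vt$a1))
  ok <- !is.na(vt$a1) & !is.na(vt$a2)
  hom <- ok & vt$a1 == vt$a2
  g[hom & vt$a1 == 0L] <- 0L
  g[hom & vt$a1 > 0L] <- 2L
  g[ok & vt$a1 != vt$a2] <- 1L
  g
}

subset_sites <- function(vt, keep) {
  variant_table(vt$sites[keep, , drop = FALSE],
                vt$a1[keep, , drop = FALSE], vt$a2[keep, , drop = FALSE],
                vt$gq[keep, , drop = FALSE], vt$dp[keep, , drop = FALSE],
                vt$panel)
}

#' Read genotypes from a VCF file
#'
#' Requires FORMAT fields GT, GQ and DP.  Multiallelic records are kept
#' (they are removed later by [apply_genotype_filters()]).
#'
#' @param path VCF v4.x file.
#' @param panel `sample_panel`; every individual must be a VCF sample.
#' @return a `variant_table`.
#' @export
read_genotype_vcf <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required to read VCF files")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1L]
  absent <- setdiff(panel$individual_id, samples)
  if (length(absent) > 0L)
    stop("panel individual(s) absent from VCF header: ",
         paste(absent, collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")[, panel$individual_id,
                                            drop = FALSE]
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)[
    , panel$individual_id, drop = FALSE]
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[
    , panel$individual_id, drop = FALSE]
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt_len <- vapply(strsplit(alt, ","), function(a) max(nchar(a)), 1L)
  is_indel <- nchar(ref) > 1L | alt_len > 1L
  indel_size <- ifelse(is_indel, abs(nchar(ref) - alt_len), NA_integer_)
  sites <- data.frame(lg_id = as.character(fix[, "CHROM"]),
                      pos = as.integer(fix[, "POS"]),
                      ref = ref, alt = alt,
                      is_indel = is_indel,
                      indel_size = as.integer(indel_size),
                      stringsAsFactors = FALSE)
  al <- parse_gt_strings(gt)
  variant_table(sites, al$a1, al$a2,
                `dimnames<-`(gq, NULL), `dimnames<-`(dp, NULL), panel)
}

parse_gt_strings <- function(gt) {
  dm <- dim(gt)
  g <- sub("\\|", "/", as.character(gt))
  parts <- strsplit(g, "/", fixed = TRUE)
  pick <- function(i) suppressWarnings(
    as.integer(vapply(parts, function(p)
      if (length(p) >= i) p[i] else NA_character_, "")))
  a1 <- pick(1L); a2 <- pick(2L)
  bad <- is.na(a1) | is.na(a2)
  a1[bad] <- NA_integer_; a2[bad] <- NA_integer_
  list(a1 = matrix(a1, dm[1], dm[2]), a2 = matrix(a2, dm[1], dm[2]))
}

# ---------------------------------------------------------------------------
# Bespoke variant-level filters
# ---------------------------------------------------------------------------

indel_mask_width <- function(size) {
  # 1 bp -> 2; 2-3 bp -> 3; 4-5 bp -> 5; >5 bp -> 10 (monotone widths)
  ifelse(size <= 1L, 2L, ifelse(size <= 3L, 3L, ifelse(size <= 5L, 5L, 10L)))
}

#' Mask SNPs around indels and drop indel records
#'
#' SNPs within `w` bp of an indel's reference span are removed, with `w`
#' depending on indel size: 2 bp for 1-bp indels, 3 bp for 2-3-bp indels,
#' 5 bp for 4-5-bp indels and 10 bp for larger ones.  Indel records
#' themselves are removed.  Idempotent.
#'
#' @param vt a `variant_table`.
#' @return filtered `variant_table` containing only SNPs.
#' @export
mask_around_indels <- function(vt) {
  s <- vt$sites
  if (nrow(s) == 0L) return(vt)
  keep <- !s$is_indel
  idx <- which(s$is_indel)
  if (length(idx) > 0L) {
    w <- indel_mask_width(s$indel_size[idx])
    lo <- s$pos[idx] - w
    hi <- s$pos[idx] + nchar(s$ref[idx]) - 1L + w
    lg <- s$lg_id[idx]
    for (k in seq_along(idx)) {
      hit <- s$lg_id == lg[k] & s$pos >= lo[k] & s$pos <= hi[k]
      keep <- keep & !hit
    }
  }
  subset_sites(vt, keep)
}

#' Genotype- and site-level quality filters
#'
#' Masks genotypes below quality/depth thresholds, then removes sites with
#' more than two alleles, sites exceeding the missing-data limit, and
#' monomorphic sites.  At sites where no retained individual carries the
#' reference allele, the first alternative allele becomes the new reference
#' and genotypes are recoded.
#'
#' @param vt a `variant_table`.
#' @param min_gq minimum genotype quality (phred); lower calls are masked.
#' @param min_dp minimum read depth; lower calls are masked.
#' @param max_missing_frac maximum tolerated fraction of missing genotypes
#'   per site.
#' @return filtered `variant_table`.
#' @export
apply_genotype_filters <- function(vt, min_gq = 20, min_dp = 4,
                                   max_missing_frac = 0.5) {
  if (n_sites(vt) == 0L) return(vt)
  low <- (!is.na(vt$gq) & vt$gq < min_gq) | (!is.na(vt$dp) & vt$dp < min_dp)
  vt$a1[low] <- NA_integer_
  vt$a2[low] <- NA_integer_
  n_alt <- vapply(strsplit(vt$sites$alt, ","), length, 1L)
  miss_frac <- rowMeans(is.na(vt$a1))
  # monomorphic = no retained genotype carries an alternative allele
  # (no variation relative to the reference)
  has_alt <- rowSums(vt$a1 > 0L, na.rm = TRUE) +
    rowSums(vt$a2 > 0L, na.rm = TRUE) > 0
  keep <- n_alt <= 1L & miss_frac <= max_missing_frac & has_alt
  vt <- subset_sites(vt, keep)
  if (n_sites(vt) == 0L) return(vt)
  # reference flipping where allele 0 is absent from retained genotypes
  has_ref <- rowSums(vt$a1 == 0L, na.rm = TRUE) +
    rowSums(vt$a2 == 0L, na.rm = TRUE) > 0
  flip <- which(!has_ref)
  if (length(flip) > 0L) {
    old_ref <- vt$sites$ref[flip]
    vt$sites$ref[flip] <- vt$sites$alt[flip]
    vt$sites$alt[flip] <- old_ref
    vt$a1[flip, ] <- 1L - vt$a1[flip, , drop = FALSE]
    vt$a2[flip, ] <- 1L - vt$a2[flip, , drop = FALSE]
  }
  vt
}

# ---------------------------------------------------------------------------
# Time trees
# ---------------------------------------------------------------------------

#' Read and validate a time-calibrated ultrametric tree
#'
#' @param path newick file containing a single rooted tree with branch
#'   lengths in million years.
#' @param tol relative tolerance for the ultrametricity check.
#' @return an `ape::phylo` tree with attribute `ultrametric` (logical);
#'   a warning is raised when root-to-tip depths differ beyond `tol`.
#' @export
read_timetree <- function(path, tol = 1e-6) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) stop("expected a single newick tree")
  if (is.null(tr) || is.null(tr$edge.length))
    stop("unparsable newick or missing branch lengths")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels in tree")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  um <- ape::is.ultrametric(tr, option = 2, tol = tol)
  if (!um) warning("tree is not ultrametric within tolerance; flagged")
  attr(tr, "ultrametric") <- um
  tr
}

#' Root-to-tip depth of an ultrametric tree (tree height, My)
#' @param tree an `ape::phylo`.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}
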