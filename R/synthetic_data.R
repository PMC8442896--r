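# Synthetic cohorts with planted sex-chromosome truth.  Background genotypes
# are i.i.d. across individuals (no population structure, no linkage); the
# planted signal is the idealised footprint each scan is designed to detect.

#' Define the planted truth of a synthetic cohort
#'
#' @param species data.frame with columns `species_id`, `sex_lg` (LG id or
#'   `NA` for no sex chromosome), `system` (`"XY"`, `"ZW"` or `"none"`),
#'   `region_start`, `region_end` (bp on `sex_lg`), `differentiation`
#'   (fraction of region sites that are sex-specific, in \[0, 1\]).
#' @param seed integer seed the cohort was / will be generated under.
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(species, seed = NA_integer_) {
  need <- c("species_id", "sex_lg", "system", "region_start", "region_end",
            "differentiation")
  if (!all(need %in% names(species)))
    stop("truth table needs columns: ", paste(need, collapse = ", "))
  if (any(species$differentiation < 0 | species$differentiation > 1,
          na.rm = TRUE))
    stop("differentiation must be in [0, 1]")
  if (!all(species$system %in% c("XY", "ZW", "none")))
    stop("system must be XY, ZW or none")
  structure(list(species = as.data.frame(species)[, need], seed = seed),
            class = "sim_truth")
}

#' Simulate a WGS cohort (one male + one female genome per species)
#'
#' Sites are placed uniformly at random on each LG.  Outside planted
#' regions genotypes are drawn independently per individual with
#' heterozygosity `background_het`; inside a planted XY region a fraction
#' `d` of sites are sex-specific (male heterozygous, female homozygous
#' reference; mirrored for ZW).  Species sharing the same (LG, region,
#' system) share the same set of sex-specific sites, emulating a shared
#' sex chromosome within a tribe.
#'
#' @param panel a `sample_panel`.
#' @param lgs an `lg_table`.
#' @param truth a `sim_truth`.
#' @param n_sites_per_lg number of variant sites per LG.
#' @param background_het per-genotype heterozygosity outside planted sites.
#' @param missing_frac fraction of genotype calls set to missing.
#' @param seed integer seed.
#' @return list with elements `vt` (a `variant_table`) and `truth` (the
#'   input truth, with the sampled sex-specific site positions attached as
#'   attribute `sex_sites`).
#' @export
simulate_wgs_cohort <- function(panel, lgs, truth, n_sites_per_lg = 2000,
                                background_het = 0.1, missing_frac = 0,
                                seed = 1) {
  set.seed(seed)
  tsp <- truth$species
  planted <- tsp[tsp$system %in% c("XY", "ZW"), , drop = FALSE]
  for (i in seq_len(nrow(planted))) {
    len <- lgs$length_bp[lgs$lg_id == planted$sex_lg[i]]
    if (length(len) != 1L || planted$region_start[i] < 1 ||
        planted$region_end[i] > len)
      stop("planted region outside LG for species ", planted$species_id[i])
    sp <- panel[panel$species_id == planted$species_id[i], ]
    if (!all(c("male", "female") %in% sp$sex))
      stop("species ", planted$species_id[i],
           " needs at least one male and one female in the panel")
  }
  sites <- do.call(rbind, lapply(seq_len(nrow(lgs)), function(k) {
    pos <- sort(sample.int(lgs$length_bp[k],
                           min(n_sites_per_lg, lgs$length_bp[k])))
    data.frame(lg_id = lgs$lg_id[k], pos = pos, stringsAsFactors = FALSE)
  }))
  n <- nrow(sites)
  ni <- nrow(panel)
  sites$ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  sites$alt <- vapply(sites$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  sites$is_indel <- FALSE
  sites$indel_size <- NA_integer_
  # background genotype codes, i.i.d. per individual
  p_hom_alt <- (1 - background_het) * 0.1
  g <- matrix(sample.int(3L, n * ni, replace = TRUE,
                         prob = c(1 - background_het - p_hom_alt,
                                  background_het, p_hom_alt)) - 1L,
              n, ni)
  # plant sex-specific sites, shared across species with the same system
  combos <- unique(planted[, c("sex_lg", "region_start", "region_end",
                               "system", "differentiation")])
  sex_sites <- list()
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    in_region <- which(sites$lg_id == cb$sex_lg &
                         sites$pos >= cb$region_start &
                         sites$pos <= cb$region_end)
    n_spec <- round(cb$differentiation * length(in_region))
    chosen <- sort(sample(in_region, n_spec))
    sex_sites[[i]] <- sites$pos[chosen]
    sel <- merge(planted, cb)$species_id
    for (spid in sel) {
      sp <- panel[panel$species_id == spid, ]
      m <- match(sp$individual_id[sp$sex == "male"][1L], panel$individual_id)
      f <- match(sp$individual_id[sp$sex == "female"][1L],
                 panel$individual_id)
      het_ind <- if (cb$system == "XY") m else f
      hom_ind <- if (cb$system == "XY") f else m
      g[chosen, het_ind] <- 1L
      g[chosen, hom_ind] <- 0L
    }
  }
  a1 <- matrix(0L, n, ni)
  a2 <- ifelse(g >= 1L, 1L, 0L)
  a1[g == 2L] <- 1L
  if (missing_frac > 0) {
    drop <- matrix(stats::runif(n * ni) < missing_frac, n, ni)
    a1[drop] <- NA_integer_
    a2[drop] <- NA_integer_
  }
  gq <- matrix(99, n, ni)
  dp <- matrix(stats::rpois(n * ni, 20) + 4L, n, ni)
  attr(truth, "sex_sites") <- sex_sites
  list(vt = variant_table(sites, a1, a2, gq, dp, panel), truth = truth)
}

#' Write a variant table as VCF v4.2
#'
#' @param vt a `variant_table`.
#' @param path output file.
#' @export
write_cohort_vcf <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", vt$panel$individual_id),
                     collapse = "\t")), con)
  gt <- matrix(paste0(ifelse(is.na(vt$a1), ".", vt$a1), "/",
                      ifelse(is.na(vt$a2), ".", vt$a2), ":",
                      vt$gq, ":", vt$dp),
               nrow(vt$a1), ncol(vt$a1))
  gt[is.na(vt$a1)] <- "./."
  lines <- paste(vt$sites$lg_id, vt$sites$pos, ".", vt$sites$ref,
                 vt$sites$alt, ".", "PASS", ".", "GT:GQ:DP",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
}

#' Simulate replicate transcriptome allele counts for one species
#'
#' Three SNP strata emulate a sexed replicate transcriptome experiment:
#' (i) plain background SNPs with sex-balanced Poisson counts on both
#' alleles; (ii) sex-biased background SNPs whose alternative allele is
#' expressed in one (random) sex only -- the autosomal sex-biased allelic
#' expression that, in real gonad-containing transcriptomes, populates the
#' genome-wide window distribution with scattered XY- and ZW-classified
#' SNPs; and (iii), when the species has a planted system, sex-specific
#' SNPs inside the true region with zero alternative-allele counts in the
#' homogametic sex and Poisson counts in the heterogametic sex (at least
#' two replicates forced non-zero, the detectability floor of the
#' classification rule).  Planted SNPs concentrate in a limited number of
#' 10-kb expressed patches (genes); background positions are uniform over
#' the genome.
#'
#' @param truth a `sim_truth`.
#' @param lgs an `lg_table`.
#' @param species_id which species of `truth` to simulate.
#' @param n_snps total number of expressed SNPs.
#' @param depth_mean mean per-replicate read depth at a SNP.
#' @param n_males,n_females replicate counts (study design default 3 + 3).
#' @param prop_sex_specific fraction of SNPs planted as sex-specific when
#'   the species has a system (they carry the sex-linkage signal).
#' @param prop_sex_biased fraction of SNPs with sex-biased background
#'   expression (random direction, not sex-linked).
#' @param n_patches number of 10-kb expressed patches the planted SNPs
#'   concentrate in.
#' @param seed integer seed.
#' @return list with `counts` (an `allele_count_table`) and `planted`
#'   (logical vector marking the planted sex-specific SNPs).
#' @export
simulate_rna_counts <- function(truth, lgs, species_id, n_snps = 2000,
                                depth_mean = 10, n_males = 3, n_females = 3,
                                prop_sex_specific = 0.1,
                                prop_sex_biased = 0.25,
                                n_patches = 20L, seed = 1) {
  stopifnot(depth_mean > 0)
  set.seed(seed)
  tr <- truth$species[truth$species$species_id == species_id, ]
  if (nrow(tr) != 1L) stop("unknown species_id in truth")
  has_sys <- tr$system %in% c("XY", "ZW")
  n_planted <- if (has_sys) round(prop_sex_specific * n_snps) else 0L
  n_biased <- round(prop_sex_biased * n_snps)
  n_bg <- n_snps - n_planted
  sex <- c(rep("male", n_males), rep("female", n_females))
  rep_id <- c(paste0("male", seq_len(n_males)),
              paste0("female", seq_len(n_females)))
  nr <- length(sex)
  if (n_snps == 0L) {
    return(list(counts = allele_count_table(
      data.frame(lg_id = character(), pos = integer()),
      matrix(0, 0, nr), matrix(0, 0, nr), sex, rep_id),
      planted = logical()))
  }
  bg_lg <- sample(lgs$lg_id, n_bg, replace = TRUE, prob = lgs$length_bp)
  bg_pos <- vapply(bg_lg, function(l)
    sample.int(lgs$length_bp[lgs$lg_id == l], 1L), 1L)
  snps <- data.frame(lg_id = bg_lg, pos = bg_pos, stringsAsFactors = FALSE)
  planted <- rep(FALSE, n_bg)
  if (n_planted > 0L) {
    # planted SNPs concentrate in a few 10-kb expressed patches (genes)
    patch_starts <- sample(seq(tr$region_start,
                               max(tr$region_start, tr$region_end - 10000L),
                           by = 10000L),
                           min(n_patches, max(1L, (tr$region_end -
                             tr$region_start) %/% 10000L)))
    patch <- sample(patch_starts, n_planted, replace = TRUE)
    ppos <- pmin(patch + sample.int(10000L, n_planted, replace = TRUE),
                 tr$region_end)
    snps <- rbind(snps, data.frame(lg_id = tr$sex_lg, pos = ppos,
                                   stringsAsFactors = FALSE))
    planted <- c(planted, rep(TRUE, n_planted))
  }
  n <- nrow(snps)
  ref <- matrix(stats::rpois(n * nr, depth_mean / 2), n, nr)
  alt <- matrix(stats::rpois(n * nr, depth_mean / 2), n, nr)
  force_two_nonzero <- function(i, cols) {
    if (sum(alt[i, cols] > 0) < 2L) {
      bump <- sample(cols, 2L)
      alt[i, bump] <<- pmax(alt[i, bump], 1)
    }
  }
  # sex-biased background: alt allele expressed in one random sex only
  if (n_biased > 0L && n_bg > 0L) {
    biased <- sample.int(n_bg, min(n_biased, n_bg))
    for (i in biased) {
      on_sex <- sample(c("male", "female"), 1L)
      off <- sex != on_sex
      alt[i, off] <- 0
      ref[i, off] <- stats::rpois(sum(off), depth_mean)
      force_two_nonzero(i, which(!off))
    }
  }
  if (n_planted > 0L) {
    het <- if (tr$system == "XY") sex == "male" else sex == "female"
    pi <- which(planted)
    alt[pi, !het] <- 0
    ref[pi, !het] <- stats::rpois(length(pi) * sum(!het), depth_mean)
    # the heterogametic sex expresses both alleles; force >= 2 replicates
    # with a non-zero alternative count so planted SNPs are classifiable
    for (i in pi) force_two_nonzero(i, which(het))
  }
  ord <- order(snps$lg_id, snps$pos)
  list(counts = allele_count_table(snps[ord, ], ref[ord, , drop = FALSE],
                                   alt[ord, , drop = FALSE], sex, rep_id),
       planted = planted[ord])
}

#' Simulate a continuous-time Markov character history along a tree
#'
#' @param tree an `ape::phylo` time tree.
#' @param states character vector of state names.
#' @param q_matrix rate matrix (per My); rows must sum to zero,
#'   off-diagonals non-negative.
#' @param root_state state at the root.
#' @param seed integer seed.
#' @return a `character_history` (see [character_history()]); tip states in
#'   `$tip_states`, per-edge state durations in `$maps`.
#' @export
simulate_trait_history <- function(tree, states, q_matrix, root_state,
                                   seed = 1) {
  q_matrix <- as.matrix(q_matrix)
  k <- length(states)
  if (!all(dim(q_matrix) == k)) stop("q_matrix must be k x k")
  if (any(q_matrix[row(q_matrix) != col(q_matrix)] < 0) ||
      any(abs(rowSums(q_matrix)) > 1e-8))
    stop("invalid q_matrix: rows must sum to 0, off-diagonals >= 0")
  dimnames(q_matrix) <- list(states, states)
  set.seed(seed)
  tree <- stats::reorder(tree)  # cladewise: parents before children
  n_tip <- length(tree$tip.label)
  node_state <- character(n_tip + tree$Nnode)
  root <- n_tip + 1L
  node_state[root] <- root_state
  maps <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    from <- node_state[tree$edge[e, 1L]]
    len <- tree$edge.length[e]
    segs <- numeric(0)
    cur <- from
    t_used <- 0
    repeat {
      rate <- -q_matrix[cur, cur]
      dt <- if (rate > 0) stats::rexp(1L, rate) else Inf
      if (t_used + dt >= len) {
        segs <- c(segs, stats::setNames(len - t_used, cur))
        break
      }
      segs <- c(segs, stats::setNames(dt, cur))
      t_used <- t_used + dt
      p <- q_matrix[cur, ]
      p[cur] <- 0
      cur <- sample(states, 1L, prob = p)
    }
    maps[[e]] <- segs
    node_state[tree$edge[e, 2L]] <- cur
  }
  character_history(tree, maps, states,
                    tip_states = stats::setNames(node_state[seq_len(n_tip)],
                                                 tree$tip.label))
}
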