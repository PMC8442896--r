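# Shared genotype-clustering engine: Gower dissimilarity on categorical
# genotype vectors + divisive hierarchical clustering, used by both the WGS
# accumulation scan and the association scan to resolve which individuals
# group by sex.

#' Gower distance between categorical genotype vectors
#'
#' For all-categorical data Gower's coefficient reduces to the simple
#' mismatch fraction over pairwise non-missing entries.
#'
#' @param m matrix with individuals in rows and sites in columns (any atomic
#'   type; `NA` allowed).
#' @return a `dist` object.
#' @export
gower_genotype_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      d[i, j] <- d[j, i] <-
        if (any(ok)) mean(m[i, ok] != m[j, ok]) else NA_real_
    }
  }
  stats::as.dist(d)
}

#' Two-group divisive clustering of individuals
#'
#' Divisive (DIANA) hierarchical clustering cut at two clusters.
#'
#' @param d a `dist` over individuals.
#' @return integer vector of cluster memberships (1/2), named by individual.
#' @export
divisive_two_cut <- function(d) {
  n <- attr(d, "Size")
  if (n < 2L) stop("need at least two individuals to cluster")
  di <- cluster::diana(d, diss = TRUE)
  stats::cutree(stats::as.hclust(di), k = 2L)
}

#' Do a male/female pair separate at the two-cluster cut?
#'
#' @param cl membership vector from [divisive_two_cut()].
#' @param male,female individual ids.
#' @return `TRUE` when both are clustered and fall in different clusters.
#' @keywords internal
pair_separates <- function(cl, male, female) {
  !is.na(cl[male]) && !is.na(cl[female]) && cl[male] != cl[female]
}
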