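# Independent oracles: brute-force enumerations and closed forms kept
# deliberately separate from the package implementations they check.

# exact p for a 2x3 table by full enumeration of the conditional
# (multivariate hypergeometric) distribution given the margins
oracle_fisher_2x3 <- function(tab) {
  stopifnot(dim(tab) == c(2L, 3L))
  r1 <- sum(tab[1L, ])
  cs <- colSums(tab)
  n <- sum(tab)
  logp_tab <- function(a, b, c) {
    lchoose(cs[1L], a) + lchoose(cs[2L], b) + lchoose(cs[3L], c) -
      lchoose(n, r1)
  }
  p_obs <- exp(logp_tab(tab[1L, 1L], tab[1L, 2L], tab[1L, 3L]))
  total <- 0
  for (a in 0:min(r1, cs[1L])) {
    for (b in 0:min(r1 - a, cs[2L])) {
      c <- r1 - a - b
      if (c > cs[3L]) next
      p <- exp(logp_tab(a, b, c))
      if (p <= p_obs * (1 + 1e-7)) total <- total + p
    }
  }
  total
}

# Mk likelihood by exhaustive enumeration over all node-state assignments
oracle_mk_enum <- function(tree, Q, tip_priors, root_prior = NULL) {
  k <- ncol(Q)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  if (!is.null(rownames(tip_priors)))
    tip_priors <- tip_priors[tree$tip.label, , drop = FALSE]
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  P <- lapply(tree$edge.length, function(t) ape::matexpo(Q * t))
  states <- as.matrix(expand.grid(rep(list(seq_len(k)), n_node)))
  lik <- 0
  for (r in seq_len(nrow(states))) {
    s <- states[r, ]
    term <- root_prior[s[n_tip + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      term <- term * P[[e]][s[tree$edge[e, 1L]], s[tree$edge[e, 2L]]]
    for (tp in seq_len(n_tip))
      term <- term * tip_priors[tp, s[tp]]
    lik <- lik + term
  }
  as.numeric(log(lik))
}

# exact two-sided Mann-Whitney p by enumeration of group assignments
oracle_mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  all_v <- c(x, y)
  combs <- utils::combn(n1 + n2, n1)
  rank_all <- rank(all_v)
  u_of <- function(idx) sum(rank_all[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  us <- apply(combs, 2L, u_of)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# exact two-sided paired signed-rank p by enumeration of sign flips
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}

# permutation oracle for the trend test: distribution of the score
# statistic under label shuffles
oracle_trend_perm_p <- function(g, y, n_perm = 20000L, seed = 99L) {
  set.seed(seed)
  ok <- !is.na(g)
  g <- g[ok]; y <- y[ok]
  stat <- function(yy) abs(sum((yy - mean(yy)) * g))
  s_obs <- stat(y)
  hits <- 0L
  for (b in seq_len(n_perm))
    if (stat(sample(y)) >= s_obs - 1e-12) hits <- hits + 1L
  hits / n_perm
}

# manual Benjamini-Hochberg adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * n / seq_len(n))))
  pmin(1, adj)[order(o)]
}
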