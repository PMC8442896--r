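# Stochastic character mapping (endpoint-conditioned via uniformization),
# turnover-point detection on along-branch posteriors, turnover and
# heterogamety transition rates, and the recruitment randomization test.

#' Sample stochastic character maps under a fitted Mk model
#'
#' Node states are sampled from their conditional posteriors (pruning
#' partials), then each branch history is sampled conditional on its
#' endpoint states by uniformization (rate 1.05 x max |Q_ii|,
#' rejection-free).
#'
#' @param fit an `mk_fit`.
#' @param n number of maps.
#' @param seed integer seed.
#' @return list of `character_history` objects.
#' @export
stochastic_maps <- function(fit, n = 1000L, seed = 1) {
  set.seed(seed)
  tree <- fit$tree
  Q <- fit$Q
  states <- fit$states
  k <- length(states)
  pr <- mk_loglik(tree, Q, fit$spm, fit$root_prior)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  preorder <- rev(ape::reorder.phylo(tree, "postorder", index.only = TRUE))
  omega <- 1.05 * max(-diag(Q))
  R <- if (omega > 0) diag(k) + Q / omega else diag(k)
  # lazily grown powers of R, shared across maps
  Rpow <- list(diag(k), R)
  get_Rpow <- function(m) {
    while (length(Rpow) < m + 1L)
      Rpow[[length(Rpow) + 1L]] <<- Rpow[[length(Rpow)]] %*% R
    Rpow[[m + 1L]]
  }
  root_post <- pr$root_prior * pr$partials[root, ]
  root_post <- root_post / sum(root_post)
  lapply(seq_len(n), function(rep) {
    node_state <- integer(n_tip + tree$Nnode)
    node_state[root] <- sample.int(k, 1L, prob = root_post)
    maps <- vector("list", nrow(tree$edge))
    for (e in preorder) {
      par <- tree$edge[e, 1L]
      chl <- tree$edge[e, 2L]
      w <- pr$P[[e]][node_state[par], ] * pr$partials[chl, ]
      node_state[chl] <- sample.int(k, 1L, prob = w)
      maps[[e]] <- sample_edge_path(
        Q, states, omega, get_Rpow, pr$P[[e]],
        node_state[par], node_state[chl], tree$edge.length[e])
    }
    character_history(tree, maps, states,
                      stats::setNames(states[node_state[seq_len(n_tip)]],
                                      tree$tip.label))
  })
}

# endpoint-conditioned path on one edge via uniformization
sample_edge_path <- function(Q, states, omega, get_Rpow, Pt, a, b, len) {
  if (omega <= 0 || len <= 0) {
    return(stats::setNames(len, states[a]))
  }
  # number of uniformized jumps
  pab <- Pt[a, b]
  u <- stats::runif(1L) * pab
  m <- 0L
  cum <- 0
  repeat {
    term <- stats::dpois(m, omega * len) * get_Rpow(m)[a, b]
    cum <- cum + term
    if (cum >= u || m > 1000L) break
    m <- m + 1L
  }
  if (m == 0L) return(stats::setNames(len, states[a]))
  # jump chain conditioned on endpoints
  path <- integer(m + 1L)
  path[1L] <- a
  path[m + 1L] <- b
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      R1 <- get_Rpow(1L)
      w <- R1[path[i], ] * get_Rpow(m - i)[, b]
      path[i + 1L] <- sample.int(length(states), 1L, prob = w)
    }
  }
  times <- c(0, sort(stats::runif(m)) * len, len)
  # collapse self-jumps into segments
  segs <- numeric(0)
  seg_state <- integer(0)
  cur <- path[1L]
  t0 <- 0
  for (i in seq_len(m)) {
    if (path[i + 1L] != cur) {
      segs <- c(segs, times[i + 1L] - t0)
      seg_state <- c(seg_state, cur)
      t0 <- times[i + 1L]
      cur <- path[i + 1L]
    }
  }
  segs <- c(segs, len - t0)
  seg_state <- c(seg_state, cur)
  stats::setNames(segs, states[seg_state])
}

# fraction of maps in `state` at grid points along every edge;
# rows = edges, columns = grid positions from parent (0) to child (1)
branch_posterior <- function(maps, state, grid = 100L) {
  tree <- maps[[1L]]$tree
  n_edge <- nrow(tree$edge)
  rel <- seq(0, 1, length.out = grid + 1L)
  acc <- matrix(0, n_edge, grid + 1L)
  for (h in maps) {
    for (e in seq_len(n_edge)) {
      m <- h$maps[[e]]
      if (length(m) == 1L) {
        if (names(m) == state) acc[e, ] <- acc[e, ] + 1
      } else {
        cuts <- cumsum(m)
        at <- rel * tree$edge.length[e]
        idx <- pmin(length(m), findInterval(at, cuts, left.open = TRUE) + 1L)
        acc[e, ] <- acc[e, ] + (names(m)[idx] == state)
      }
    }
  }
  acc / length(maps)
}

#' Detect turnover points from stochastic maps
#'
#' For a focal state (one LG used as a sex chromosome, coded as a binary
#' trait), the along-branch posterior is evaluated on a grid (100 points
#' per branch).  From every tip in the focal state, walking rootward, the
#' first crossing of the posterior below `threshold` is the turnover
#' (gain) point; crossings are deduplicated per branch.  A path on which
#' the posterior never drops below the threshold yields a single event at
#' the root edge flagged `root_or_earlier`.
#'
#' @param maps list of `character_history` from [stochastic_maps()].
#' @param state focal state name.
#' @param tip_in_state logical vector (named by tip) marking tips carrying
#'   the state; defaults to tips whose realised state equals `state` in
#'   more than half the maps.
#' @param threshold posterior cutoff (0.5).
#' @param grid points per branch.
#' @return data.frame of gain events: `edge`, `time_my` (before present),
#'   `state`, `root_or_earlier`.
#' @export
detect_turnovers <- function(maps, state, tip_in_state = NULL,
                             threshold = 0.5, grid = 100L) {
  stopifnot(length(maps) > 0L)
  tree <- maps[[1L]]$tree
  n_tip <- length(tree$tip.label)
  if (is.null(tip_in_state)) {
    frac <- rowMeans(vapply(maps, function(h)
      h$tip_states == state, logical(n_tip)))
    tip_in_state <- stats::setNames(frac >= 0.5, tree$tip.label)
  }
  post <- branch_posterior(maps, state, grid)
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(n_tip)])
  parent_of <- function(node) {
    e <- which(tree$edge[, 2L] == node)
    if (length(e) == 0L) NA_integer_ else e
  }
  events <- list()
  for (tip in which(tip_in_state)) {
    node <- tip
    found <- FALSE
    repeat {
      e <- parent_of(node)
      if (is.na(e)) break
      pv <- post[e, ]                     # index 1 = parent end
      below <- which(pv < threshold)
      if (length(below) > 0L) {
        j <- max(below)                   # first crossing walking rootward
        if (j == length(pv)) {            # below already at the child end
          frac_pos <- 1
        } else {
          p_lo <- pv[j]; p_hi <- pv[j + 1L]
          f <- if (p_hi > p_lo) (threshold - p_lo) / (p_hi - p_lo) else 0
          frac_pos <- (j - 1L + f) / grid
        }
        t_par <- height - depth[tree$edge[e, 1L]]
        t_chl <- height - depth[tree$edge[e, 2L]]
        events[[length(events) + 1L]] <- data.frame(
          edge = e, time_my = t_par - frac_pos * (t_par - t_chl),
          state = state, root_or_earlier = FALSE)
        found <- TRUE
        break
      }
      node <- tree$edge[e, 1L]
    }
    if (!found) {
      root_edges <- which(tree$edge[, 1L] == n_tip + 1L)
      events[[length(events) + 1L]] <- data.frame(
        edge = root_edges[1L], time_my = height, state = state,
        root_or_earlier = TRUE)
    }
  }
  if (length(events) == 0L)
    return(data.frame(edge = integer(), time_my = numeric(),
                      state = character(), root_or_earlier = logical()))
  ev <- do.call(rbind, events)
  # one event per branch per state
  ev <- ev[!duplicated(ev[, c("edge", "state")]), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Turnover rate per lineage-million-years
#'
#' Rate = number of events / total branch length of the tree (the tree
#' height is available as an alternative denominator).  Also reports the
#' expected divergence time between two species separated by one event,
#' t = 1 / (2 rate): two diverging lineages accumulate events at twice the
#' per-lineage rate.
#'
#' @param events event data.frame (or an event count).
#' @param tree the time tree the events were detected on.
#' @param denominator `"tree_length"` or `"height"`.
#' @return list: `n_events`, `rate_per_my`, `expected_divergence_my`.
#' @export
estimate_rate <- function(events, tree,
                          denominator = c("tree_length", "height")) {
  denominator <- match.arg(denominator)
  n_ev <- if (is.data.frame(events)) nrow(events) else as.integer(events)
  denom <- if (denominator == "tree_length") sum(tree$edge.length)
    else tree_height(tree)
  if (denom <= 0) stop("tree has zero total length")
  rate <- n_ev / denom
  list(n_events = n_ev, rate_per_my = rate,
       expected_divergence_my = if (rate > 0) 1 / (2 * rate) else Inf)
}

#' Reconstruct heterogamety transitions
#'
#' Runs the Mk/stochastic-mapping machinery over heterogamety states
#' (XY/ZW, optionally NonGSD), detects gain points per state, infers each
#' gain's source state from the posterior just rootward of the crossing,
#' and reports per-direction counts, event ages and the transition rate.
#' Literature-driven extra events (e.g. a documented within-species
#' system change) can be injected and are counted into the rate.
#'
#' @param tree time tree.
#' @param spm tips x heterogamety-states probability matrix.
#' @param n_maps stochastic maps to draw.
#' @param seed integer seed.
#' @param extra_events optional data.frame with columns `from`, `to`,
#'   `time_my` appended to the transition list.
#' @param grid grid points per branch.
#' @return list: `transitions` (data.frame `edge`, `time_my`, `from`,
#'   `to`), `counts` (named per-direction), `rate_per_my`, `fit`, `maps`.
#' @export
heterogamety_transitions <- function(tree, spm, n_maps = 1000L, seed = 1,
                                     extra_events = NULL, grid = 100L) {
  sel <- fit_mk_models(tree, spm)
  maps <- stochastic_maps(sel$best, n = n_maps, seed = seed)
  states <- colnames(spm)
  trans <- list()
  for (s in intersect(states, c("XY", "ZW"))) {
    ev <- detect_turnovers(maps, s, grid = grid)
    if (nrow(ev) == 0L) next
    for (i in seq_len(nrow(ev))) {
      from <- source_state_at(maps, ev$edge[i], ev$time_my[i], s, grid)
      trans[[length(trans) + 1L]] <- data.frame(
        edge = ev$edge[i], time_my = ev$time_my[i], from = from, to = s,
        root_or_earlier = ev$root_or_earlier[i])
    }
  }
  transitions <- if (length(trans) > 0L) do.call(rbind, trans)
    else data.frame(edge = integer(), time_my = numeric(),
                    from = character(), to = character(),
                    root_or_earlier = logical())
  transitions <- transitions[!is.na(transitions$from) &
                               transitions$from != transitions$to, ,
                             drop = FALSE]
  if (!is.null(extra_events) && nrow(extra_events) > 0L) {
    extra <- data.frame(edge = NA_integer_, time_my = extra_events$time_my,
                        from = extra_events$from, to = extra_events$to,
                        root_or_earlier = FALSE)
    transitions <- rbind(transitions, extra)
  }
  dirs <- paste(transitions$from, transitions$to, sep = "->")
  counts <- table(factor(dirs, levels = unique(c("XY->ZW", "ZW->XY",
                                                 dirs))))
  rate <- nrow(transitions) / sum(tree$edge.length)
  list(transitions = transitions, counts = counts, rate_per_my = rate,
       fit = sel$best, aic = sel$aic, maps = maps)
}

# dominant non-focal state just rootward of a crossing point
source_state_at <- function(maps, edge, time_my, focal, grid = 100L) {
  tree <- maps[[1L]]$tree
  states <- maps[[1L]]$states
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(length(tree$tip.label))])
  t_par <- height - depth[tree$edge[edge, 1L]]
  t_chl <- height - depth[tree$edge[edge, 2L]]
  len <- tree$edge.length[edge]
  # position slightly rootward of the event on this edge
  at <- max(0, (t_par - time_my) / max(t_par - t_chl, 1e-12) * len -
              len / grid)
  other <- setdiff(states, focal)
  freq <- vapply(other, function(s)
    mean(vapply(maps, function(h) state_at(h, edge, at) == s, TRUE)), 1.0)
  if (all(freq == 0)) NA_character_ else other[which.max(freq)]
}

#' Label LG turnovers as heterogamety-preserving or -changing
#'
#' Each sex-chromosome (LG) turnover event is compared to the heterogamety
#' reconstruction: dominant heterogamety just rootward vs just tipward of
#' the event point.  Also lists heterogamety transitions on branches with
#' no LG turnover.
#'
#' @param lg_events turnover events (from [detect_turnovers()], possibly
#'   concatenated over LGs) with columns `edge`, `time_my`.
#' @param het heterogamety result from [heterogamety_transitions()].
#' @param grid grid points per branch.
#' @return list: `lg_events` with a `heterogamety` column
#'   (`"preserving"`/`"changing"`), `uncoupled` heterogamety transitions.
#' @export
label_turnover_heterogamety <- function(lg_events, het, grid = 100L) {
  maps <- het$maps
  tree <- maps[[1L]]$tree
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(length(tree$tip.label))])
  lab <- character(nrow(lg_events))
  for (i in seq_len(nrow(lg_events))) {
    e <- lg_events$edge[i]
    t_par <- height - depth[tree$edge[e, 1L]]
    t_chl <- height - depth[tree$edge[e, 2L]]
    len <- tree$edge.length[e]
    pos <- (t_par - lg_events$time_my[i]) /
      max(t_par - t_chl, 1e-12) * len
    before <- dominant_state(maps, e, max(0, pos - len / grid))
    after <- dominant_state(maps, e, min(len, pos + len / grid))
    lab[i] <- if (identical(before, after)) "preserving" else "changing"
  }
  lg_events$heterogamety <- lab
  uncoupled <- het$transitions[!het$transitions$edge %in% lg_events$edge, ,
                               drop = FALSE]
  list(lg_events = lg_events, uncoupled = uncoupled)
}

dominant_state <- function(maps, edge, at) {
  st <- vapply(maps, function(h) state_at(h, edge, at), "")
  names(sort(table(st), decreasing = TRUE))[1L]
}

#' Compare ages of transitions by direction
#'
#' Two-sided Mann-Whitney U test of event ages between the two transition
#' directions (exact for small samples without ties).
#'
#' @param transitions data.frame from [heterogamety_transitions()] with
#'   columns `from`, `to`, `time_my`.
#' @param dir1,dir2 the two directions, as `c(from, to)`.
#' @return list: `p_value`, `n1`, `n2`, `median1`, `median2`, `message`.
#' @export
compare_transition_ages <- function(transitions,
                                    dir1 = c("XY", "ZW"),
                                    dir2 = c("ZW", "XY")) {
  a1 <- transitions$time_my[transitions$from == dir1[1L] &
                              transitions$to == dir1[2L]]
  a2 <- transitions$time_my[transitions$from == dir2[1L] &
                              transitions$to == dir2[2L]]
  if (length(a1) == 0L || length(a2) == 0L)
    return(list(p_value = NA_real_, n1 = length(a1), n2 = length(a2),
                median1 = NA_real_, median2 = NA_real_,
                message = "one direction has no events; no test"))
  p <- if (length(unique(c(a1, a2))) == 1L) 1 else
    suppressWarnings(stats::wilcox.test(a1, a2,
                                        alternative = "two.sided")$p.value)
  list(p_value = p, n1 = length(a1), n2 = length(a2),
       median1 = stats::median(a1), median2 = stats::median(a2),
       message = "ok")
}

#' Recruitment randomization test
#'
#' Each simulation draws `n_events` 10-kb windows uniformly over the
#' genome (LG chosen with probability proportional to its length) and
#' assigns the containing LG as a recruited sex chromosome.  Reports the
#' fraction of simulations in which at least `observed_never` LGs were
#' never recruited, and the per-LG recruitment distribution.
#'
#' @param n_events number of recruitment events per simulation.
#' @param lgs an `lg_table`.
#' @param n_sim number of simulations.
#' @param observed_never observed count of never-recruited LGs.
#' @param seed integer seed.
#' @return list: `fraction` (simulations with >= `observed_never`
#'   never-recruited LGs), `never_counts` (per simulation), `per_lg_mean`,
#'   `per_lg_counts` (n_sim x LG matrix).
#' @export
random_recruitment_test <- function(n_events, lgs, n_sim = 10000L,
                                    observed_never, seed = 1) {
  if (n_events <= 0L) stop("n_events must be positive")
  set.seed(seed)
  n_lg <- nrow(lgs)
  draws <- sample.int(n_lg, n_sim * n_events, replace = TRUE,
                      prob = lgs$length_bp)
  counts <- matrix(unlist(lapply(
    split(draws, rep(seq_len(n_sim), each = n_events)),
    tabulate, nbins = n_lg), use.names = FALSE),
    nrow = n_sim, ncol = n_lg, byrow = TRUE)
  colnames(counts) <- lgs$lg_id
  never <- rowSums(counts == 0L)
  list(fraction = mean(never >= observed_never),
       never_counts = never,
       per_lg_mean = colMeans(counts),
       per_lg_counts = counts)
}
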