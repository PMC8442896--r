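test_that("pruning likelihood equals exhaustive enumeration on small trees", {
  set.seed(21)
  for (i in 1:6) {
    n_tip <- sample(3:5, 1L)
    k <- sample(2:3, 1L)
    tr <- ultra_tree(n_tip, height = sample(2:8, 1L), seed = 100 + i)
    Q <- matrix(runif(k * k, 0.01, 0.3), k, k)
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
    # soft tip priors
    pri <- matrix(runif(n_tip * k), n_tip, k)
    pri <- pri / rowSums(pri)
    rownames(pri) <- tr$tip.label
    colnames(pri) <- paste0("st", seq_len(k))
    expect_equal(mk_loglik(tr, Q, pri)$loglik, oracle_mk_enum(tr, Q, pri),
                 tolerance = 1e-8)
  }
})

test_that("two-tip likelihood matches the matrix-exponential closed form", {
  tr <- ape::read.tree(text = "(A:1.5,B:1.5);")
  q <- 0.2
  Q <- matrix(c(-q, q, q, -q), 2, 2)
  pri <- rbind(A = c(1, 0), B = c(0, 1))
  # direct arithmetic: sum over root states of prior x two tip transitions
  P <- ape::matexpo(Q * 1.5)
  lik <- sum(0.5 * P[, 1] * P[, 2])
  expect_equal(mk_loglik(tr, Q, pri)$loglik, log(lik), tolerance = 1e-10)
})

test_that("uniform data drive rates to the zero boundary", {
  tr <- ultra_tree(6, height = 5, seed = 2)
  pri <- state_probability_matrix(tr$tip.label, c("a", "b"),
                                  setNames(rep("a", 6), tr$tip.label))
  f <- fit_mk(tr, pri, "ER")
  expect_lt(f$rates[1L], 1e-6)
  expect_gt(f$loglik, log(0.5) - 1e-6)  # root prior is the only cost
})

test_that("model selection respects likelihood nesting and AIC ties", {
  tr <- ultra_tree(10, height = 10, seed = 5)
  h <- simulate_trait_history(tr, c("a", "b", "c"),
                              matrix(c(-0.2, 0.1, 0.1,
                                       0.1, -0.2, 0.1,
                                       0.1, 0.1, -0.2), 3, byrow = TRUE),
                              "a", seed = 4)
  pri <- state_probability_matrix(tr$tip.label, c("a", "b", "c"),
                                  h$tip_states)
  sel <- fit_mk_models(tr, pri)
  ll <- vapply(sel$fits, `[[`, 1.0, "loglik")
  expect_gte(ll[["SYM"]], ll[["ER"]] - 1e-4)
  expect_gte(ll[["ARD"]], ll[["SYM"]] - 1e-4)
  k <- c(ER = 1, SYM = 3, ARD = 6)
  expect_equal(unname(sel$aic), unname(2 * k - 2 * ll))
})

test_that("the Mk fit agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- ultra_tree(12, height = 10, seed = 9)
  h <- simulate_trait_history(tr, c("a", "b"),
                              matrix(c(-0.1, 0.1, 0.05, -0.05), 2,
                                     byrow = TRUE), "a", seed = 3)
  pri <- state_probability_matrix(tr$tip.label, c("a", "b"), h$tip_states)
  f <- fit_mk(tr, pri, "ARD")
  pf <- phytools::fitMk(tr, h$tip_states[tr$tip.label], model = "ARD",
                        pi = "equal")
  expect_equal(f$loglik, as.numeric(stats::logLik(pf)), tolerance = 1e-3)
})

test_that("stochastic maps are deterministic, consistent and calibrated", {
  tr <- ultra_tree(4, height = 6, seed = 12)
  states <- c("a", "b")
  h <- simulate_trait_history(tr, states,
                              matrix(c(-0.15, 0.15, 0.15, -0.15), 2),
                              "a", seed = 8)
  pri <- state_probability_matrix(tr$tip.label, states, h$tip_states)
  f <- fit_mk(tr, pri, "ER")
  m1 <- stochastic_maps(f, n = 20, seed = 4)
  m2 <- stochastic_maps(f, n = 20, seed = 4)
  expect_identical(m1, m2)
  # every map is consistent with its sampled tip states and edge lengths
  for (h2 in m1) {
    lens <- vapply(h2$maps, sum, 1.0)
    expect_equal(lens, tr$edge.length, tolerance = 1e-9)
  }
  # near-zero rates give change-free maps
  f0 <- f
  f0$Q <- matrix(c(-1e-12, 1e-12, 1e-12, -1e-12), 2,
                 dimnames = dimnames(f$Q))
  f0$spm <- state_probability_matrix(tr$tip.label, states,
                                     setNames(rep("a", 4), tr$tip.label))
  m0 <- stochastic_maps(f0, n = 10, seed = 1)
  expect_true(all(vapply(m0, n_changes, 0L) == 0L))
  # node-state frequencies match the enumeration posterior
  post_or <- function(tree, Q, pri, node) {
    # enumeration: posterior of each state at an internal node
    k <- ncol(Q)
    n_tip <- length(tree$tip.label)
    P <- lapply(tree$edge.length, function(t) ape::matexpo(Q * t))
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)),
                                      n_tip + tree$Nnode)))
    w <- apply(grid, 1L, function(s) {
      term <- 1 / k
      for (e in seq_len(nrow(tree$edge)))
        term <- term * P[[e]][s[tree$edge[e, 1L]], s[tree$edge[e, 2L]]]
      for (tp in seq_len(n_tip)) term <- term * pri[tp, s[tp]]
      term
    })
    vapply(seq_len(k), function(st)
      sum(w[grid[, node] == st]) / sum(w), 1.0)
  }
  maps <- stochastic_maps(f, n = 3000, seed = 6)
  node <- 6L  # an internal node of the 4-tip tree
  freq <- mean(vapply(maps, function(hh)
    history_node_states(hh)[node] == "a", TRUE))
  expect_lt(abs(freq - post_or(tr, f$Q, pri, node)[1L]), 0.02)
})

test_that("map change counts match the analytic event rate without data", {
  tr <- ultra_tree(6, height = 8, seed = 3)
  q <- 0.06
  states <- c("a", "b")
  pri <- state_probability_matrix(tr$tip.label, states)  # uninformative
  f <- structure(list(model = "ER", rates = q,
                      Q = matrix(c(-q, q, q, -q), 2,
                                 dimnames = list(states, states)),
                      states = states, tree = tr, spm = pri,
                      root_prior = "uniform"), class = "mk_fit")
  maps <- stochastic_maps(f, n = 4000, seed = 10)
  counts <- vapply(maps, n_changes, 0L)
  expected <- q * sum(tr$edge.length)   # stationary symmetric chain
  expect_lt(abs(mean(counts) - expected) / expected, 0.10)
})

test_that("turnover detection finds planted gains on true histories", {
  tr <- ape::read.tree(text = "((A:2,B:2):3,(C:2,D:2):3);")
  states <- c("no", "yes")
  # single gain on the stem of (A,B): one event, not two
  maps <- list(character_history(
    tr,
    list(setNames(c(1.5, 1.5), c("no", "yes")),  # stem of (A,B)
         setNames(2, "yes"),                      # A
         setNames(2, "yes"),                      # B
         setNames(3, "no"), setNames(2, "no"), setNames(2, "no")),
    states, setNames(c("yes", "yes", "no", "no"), c("A", "B", "C", "D"))))
  ev <- detect_turnovers(maps, "yes")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$edge, 1L)
  expect_false(ev$root_or_earlier)
  # crossing time: the state flips 1.5 My into a branch spanning 5..2 My
  expect_equal(ev$time_my, 3.5, tolerance = 0.1)
  # a tip matching the root state throughout yields no event
  ev_no <- detect_turnovers(maps, "no")
  expect_equal(sum(!ev_no$root_or_earlier), 0L)
})

test_that("single planted turnovers localise to the true branch", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    tr <- ultra_tree(20, height = 10, seed = 500 + s)
    # plant a gain on the longest stem of a mid-sized clade: localisation
    # to one branch is only well-posed when the stem is appreciable
    n_tip <- 20L
    internal <- which(tr$edge[, 2L] > n_tip)
    clade_sizes <- vapply(tr$edge[internal, 2L], function(nd)
      length(ape::extract.clade(tr, nd)$tip.label), 1L)
    elig <- internal[clade_sizes >= 3 & clade_sizes <= 5]
    pick <- elig[which.max(tr$edge.length[elig])]
    if (length(pick) == 0L) next
    clade <- ape::extract.clade(tr, tr$edge[pick, 2L])$tip.label
    tips <- setNames(ifelse(tr$tip.label %in% clade, "yes", "no"),
                     tr$tip.label)
    pri <- state_probability_matrix(tr$tip.label, c("no", "yes"), tips)
    f <- fit_mk(tr, pri, "ER")
    maps <- stochastic_maps(f, n = 200, seed = s)
    ev <- detect_turnovers(maps, "yes")
    if (nrow(ev) == 1L && ev$edge == pick) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("turnover rates and the divergence-time identity are exact", {
  tr <- ultra_tree(5, height = 5, seed = 6)
  tr$edge.length <- tr$edge.length * 30 / sum(tr$edge.length)
  r <- estimate_rate(3L, tr)
  expect_equal(r$rate_per_my, 0.1)
  expect_equal(r$expected_divergence_my, 5)
  # the published rate implies one turnover between species ~2.7 My apart
  r2 <- estimate_rate(93L, ultra_tree(5, height = 5, seed = 1) |>
                        (\(t) {t$edge.length <-
                          t$edge.length * 500 / sum(t$edge.length); t})())
  expect_equal(r2$rate_per_my, 0.186)
  expect_equal(r2$expected_divergence_my, 2.688, tolerance = 1e-3)
  tr0 <- tr
  tr0$edge.length <- tr0$edge.length * 0
  expect_error(estimate_rate(1L, tr0), "zero")
})

test_that("planted Markov rates are recovered by inference", {
  q <- 0.05
  Q <- matrix(c(-q, q, q, -q), 2)
  est <- rep(NA_real_, 20)
  for (s in 1:20) {
    tr <- ultra_tree(20, height = 10, seed = 700 + s)
    h <- simulate_trait_history(tr, c("a", "b"), Q, "a", seed = s)
    pri <- state_probability_matrix(tr$tip.label, c("a", "b"),
                                    h$tip_states)
    est[s] <- fit_mk(tr, pri, "ER")$rates[1L]
  }
  expect_true(q >= quantile(est, 0.025) && q <= quantile(est, 0.975))
  expect_lt(abs(median(est) - q) / q, 1)
})

test_that("heterogamety transitions recover direction and clade", {
  hits <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    tr <- ultra_tree(14, height = 10, seed = 900 + s)
    # the direction of a change on a root-attached clade is unidentifiable
    # under a symmetric model, so plant below the root on a long stem
    n_tip <- 14L
    internal <- which(tr$edge[, 2L] > n_tip & tr$edge[, 1L] != n_tip + 1L)
    clade_sizes <- vapply(tr$edge[internal, 2L], function(nd)
      length(ape::extract.clade(tr, nd)$tip.label), 1L)
    elig <- internal[clade_sizes >= 3 & clade_sizes <= 6]
    pick <- elig[which.max(tr$edge.length[elig])]
    if (length(pick) == 0L) next
    clade <- ape::extract.clade(tr, tr$edge[pick, 2L])$tip.label
    tips <- setNames(ifelse(tr$tip.label %in% clade, "ZW", "XY"),
                     tr$tip.label)
    spm <- state_probability_matrix(tr$tip.label, c("XY", "ZW"), tips)
    het <- heterogamety_transitions(tr, spm, n_maps = 200, seed = s)
    tx <- het$transitions[!het$transitions$root_or_earlier, , drop = FALSE]
    if (nrow(tx) >= 1L && any(tx$edge == pick & tx$from == "XY" &
                                tx$to == "ZW")) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
  # all-XY tips yield no transitions
  tr <- ultra_tree(6, height = 5, seed = 1)
  spm <- state_probability_matrix(tr$tip.label, c("XY", "ZW"),
                                  setNames(rep("XY", 6), tr$tip.label))
  het0 <- heterogamety_transitions(tr, spm, n_maps = 50, seed = 1)
  expect_equal(nrow(het0$transitions), 0L)
})

test_that("transition-age comparisons match the exact U distribution", {
  tx <- data.frame(from = c(rep("XY", 3), rep("ZW", 3)),
                   to = c(rep("ZW", 3), rep("XY", 3)),
                   time_my = c(1, 2, 3, 10, 11, 12))
  out <- compare_transition_ages(tx)
  expect_equal(out$p_value,
               oracle_mann_whitney(c(1, 2, 3), c(10, 11, 12)),
               tolerance = 1e-9)
  # identical multisets -> p = 1
  tx2 <- data.frame(from = c("XY", "ZW"), to = c("ZW", "XY"),
                    time_my = c(2, 2))
  expect_equal(suppressWarnings(compare_transition_ages(tx2)$p_value), 1)
  # an empty direction -> message, no test
  tx3 <- tx[1:3, ]
  expect_match(compare_transition_ages(tx3)$message, "no events")
})

test_that("the recruitment test matches binomial expectations", {
  lgs <- make_lgs(23, 1000000L, ids = paste0("L", 1:23))
  rt <- random_recruitment_test(30L, lgs, n_sim = 4000L,
                                observed_never = 10L, seed = 2)
  expected_never <- 23 * (22 / 23)^30
  se <- sd(rt$never_counts) / sqrt(length(rt$never_counts))
  expect_lt(abs(mean(rt$never_counts) - expected_never), 3 * se)
  # per-LG mean recruitment proportional to length
  lgs2 <- lg_table(data.frame(lg_id = c("a", "b"),
                              length_bp = c(3000000L, 1000000L)))
  rt2 <- random_recruitment_test(40L, lgs2, n_sim = 4000L,
                                 observed_never = 1L, seed = 3)
  expect_equal(unname(rt2$per_lg_mean[1] / rt2$per_lg_mean[2]), 3,
               tolerance = 0.1)
  # a single LG can never be missed
  rt1 <- random_recruitment_test(5L, lgs2[1, ], n_sim = 100L,
                                 observed_never = 1L, seed = 1)
  expect_equal(rt1$fraction, 0)
  # determinism
  rt3 <- random_recruitment_test(30L, lgs, n_sim = 500L,
                                 observed_never = 10L, seed = 7)
  rt4 <- random_recruitment_test(30L, lgs, n_sim = 500L,
                                 observed_never = 10L, seed = 7)
  expect_identical(rt3, rt4)
  expect_error(random_recruitment_test(0L, lgs, observed_never = 1L),
               "positive")
})

test_that("pGLS equals OLS on star phylogenies and is calibrated", {
  star <- ape::stree(12, "star")
  star$edge.length <- rep(2, 12)
  star$tip.label <- paste0("t", 1:12)
  set.seed(3)
  x <- setNames(rnorm(12), star$tip.label)
  y <- 1.5 * x + setNames(rnorm(12, 0, 0.3), star$tip.label)
  pf <- pgls_fit(y, x, star)
  of <- summary(stats::lm(y[star$tip.label] ~ x[star$tip.label]))
  expect_equal(pf$coefficient, unname(of$coefficients[2L, 1L]),
               tolerance = 1e-8)
  expect_equal(pf$p_value, unname(of$coefficients[2L, 4L]),
               tolerance = 1e-8)
  # exact linear relation
  y2 <- setNames(2 * x, names(x))
  pf2 <- pgls_fit(y2, x, star)
  expect_equal(pf2$coefficient, 2, tolerance = 1e-8)
  expect_lt(pf2$p_value, 1e-12)
  # agreement with the reference GLS implementation on a non-star tree
  skip_if_not_installed("nlme")
  tr_b <- ultra_tree(10, height = 4, seed = 8)
  set.seed(9)
  xb0 <- setNames(rnorm(10), tr_b$tip.label)
  yb0 <- 0.8 * xb0 + setNames(rnorm(10, 0, 0.5), tr_b$tip.label)
  pf_b <- pgls_fit(yb0, xb0, tr_b)
  d <- data.frame(sp = tr_b$tip.label, y = yb0, x = xb0)
  gf <- nlme::gls(y ~ x, data = d,
                  correlation = ape::corBrownian(1, tr_b, form = ~sp))
  tt <- summary(gf)$tTable
  expect_equal(pf_b$coefficient, unname(tt["x", "Value"]),
               tolerance = 1e-6)
  expect_equal(pf_b$p_value, unname(tt["x", "p-value"]), tolerance = 1e-6)
  # type-I error under Brownian-motion y independent of x
  tr <- ultra_tree(15, height = 5, seed = 4)
  V <- ape::vcv(tr)
  rej <- 0L
  for (s in 1:50) {
    set.seed(1000 + s)
    yb <- setNames(as.numeric(MASS::mvrnorm(1, rep(0, 15), V)),
                   tr$tip.label)
    xb <- setNames(as.numeric(MASS::mvrnorm(1, rep(0, 15), V)),
                   tr$tip.label)
    if (pgls_fit(yb, xb, tr)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 50, 0.01)
  expect_lte(rej / 50, 0.12)
})
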