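# Mk-model machinery: discrete-state continuous-time Markov models of
# character evolution on a time tree, with soft (probability-row) tip
# priors, fitted by maximum likelihood via Felsenstein pruning.

#' Construct a character history (one stochastic map realisation)
#'
#' @param tree an `ape::phylo`.
#' @param maps list over tree edges; each element a named numeric vector of
#'   state durations along the edge (parent to child, summing to the edge
#'   length).
#' @param states state names.
#' @param tip_states named character vector of realised tip states.
#' @return object of class `character_history`.
#' @export
character_history <- function(tree, maps, states, tip_states) {
  stopifnot(length(maps) == nrow(tree$edge))
  structure(list(tree = tree, maps = maps, states = states,
                 tip_states = tip_states),
            class = "character_history")
}

#' Number of state changes in a character history
#' @param h a `character_history`.
#' @export
n_changes <- function(h) {
  sum(vapply(h$maps, function(m) sum(names(m)[-1] != names(m)[-length(m)]),
             0L))
}

#' State at a given position along an edge of a character history
#' @param h a `character_history`.
#' @param edge edge index (row of `tree$edge`).
#' @param at distance from the parent end of the edge.
#' @export
state_at <- function(h, edge, at) {
  m <- h$maps[[edge]]
  names(m)[min(length(m), findInterval(at, cumsum(m), left.open = TRUE) + 1L)]
}

#' Build a tip state-probability matrix
#'
#' Species with a known state get probability 1 on it; species without
#' information get the uniform row.
#'
#' @param tips tip labels (matrix rows, in this order).
#' @param states state names (matrix columns).
#' @param known named character vector of known tip states (subset of
#'   `tips`).
#' @return tips x states probability matrix, rows summing to 1.
#' @export
state_probability_matrix <- function(tips, states, known = character()) {
  m <- matrix(1 / length(states), length(tips), length(states),
              dimnames = list(tips, states))
  for (tp in names(known)) {
    m[tp, ] <- 0
    m[tp, known[[tp]]] <- 1
  }
  m
}

build_Q <- function(par, k, model) {
  Q <- matrix(0, k, k)
  off <- row(Q) != col(Q)
  if (model == "ER") {
    Q[off] <- par[1L]
  } else if (model == "SYM") {
    idx <- 0L
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      idx <- idx + 1L
      Q[i, j] <- Q[j, i] <- par[idx]
    }
  } else {
    Q[off] <- par  # ARD, column-major over off-diagonal entries
  }
  diag(Q) <- -rowSums(Q)
  Q
}

n_free_rates <- function(k, model) {
  switch(model, ER = 1L, SYM = k * (k - 1L) / 2L, ARD = k * (k - 1L))
}

# edge transition-probability matrices for a fitted/candidate Q
edge_probs <- function(Q, lens) {
  lapply(lens, function(t) ape::matexpo(Q * t))
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' @param tree an `ape::phylo`.
#' @param Q rate matrix (states x states, rows summing to 0).
#' @param tip_priors tips x states probability matrix (soft tip states),
#'   rows in `tree$tip.label` order or named by tip.
#' @param root_prior `"uniform"` or a probability vector over states.
#' @return list: `loglik`, plus the per-node scaled partial likelihoods
#'   (`partials`), per-node log scale factors and per-edge probability
#'   matrices, reused by the stochastic mapper.
#' @export
mk_loglik <- function(tree, Q, tip_priors, root_prior = "uniform") {
  k <- ncol(Q)
  n_tip <- length(tree$tip.label)
  if (!is.null(rownames(tip_priors)))
    tip_priors <- tip_priors[tree$tip.label, , drop = FALSE]
  stopifnot(nrow(tip_priors) == n_tip, ncol(tip_priors) == k)
  P <- edge_probs(Q, tree$edge.length)
  post <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  L <- matrix(1, n_tip + tree$Nnode, k)
  L[seq_len(n_tip), ] <- tip_priors
  logscale <- 0
  for (e in post) {
    par <- tree$edge[e, 1L]
    chl <- tree$edge[e, 2L]
    msg <- as.numeric(P[[e]] %*% L[chl, ])
    L[par, ] <- L[par, ] * msg
    mx <- max(L[par, ])
    if (mx > 0 && mx < 1e-10) {
      L[par, ] <- L[par, ] / mx
      logscale <- logscale + log(mx)
    }
  }
  root <- n_tip + 1L
  pi0 <- if (identical(root_prior, "uniform")) rep(1 / k, k) else root_prior
  lik <- sum(pi0 * L[root, ])
  if (!is.finite(lik) || lik < 0)
    stop("non-finite Mk likelihood")
  list(loglik = log(lik) + logscale, partials = L, P = P,
       root_prior = pi0)
}

#' Fit an Mk model by maximum likelihood
#'
#' Rates are optimised with bounded quasi-Newton (`L-BFGS-B`) from two
#' starting values; the root prior is uniform over states (matching the
#' equal-probability coding of uninformative tips).
#'
#' @param tree an `ape::phylo` time tree.
#' @param spm tips x states probability matrix
#'   (see [state_probability_matrix()]).
#' @param model `"ER"` (equal rates), `"SYM"` (symmetric) or `"ARD"` (all
#'   rates different).
#' @param root_prior as in [mk_loglik()].
#' @return object of class `mk_fit`: `model`, `Q` (per My), `rates`,
#'   `loglik`, `aic`, `k_rates`, plus `tree`, `spm`, `root_prior` for
#'   downstream mapping.
#' @export
fit_mk <- function(tree, spm, model = c("ER", "SYM", "ARD"),
                   root_prior = "uniform") {
  model <- match.arg(model)
  k <- ncol(spm)
  stopifnot(k >= 2L)
  states <- colnames(spm)
  npar <- n_free_rates(k, model)
  nll <- function(par) {
    ll <- tryCatch(
      mk_loglik(tree, build_Q(par, k, model), spm, root_prior)$loglik,
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  init <- 1 / max(tree_height(tree), 1e-6)
  best <- NULL
  for (start in c(init, init * 10)) {
    opt <- stats::optim(rep(start, npar), nll, method = "L-BFGS-B",
                        lower = rep(1e-9, npar), upper = rep(1e4, npar),
                        control = list(maxit = 500L))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (best$value >= 1e10)
    stop("Mk optimisation failed to find a finite likelihood")
  loglik <- -best$value
  structure(list(model = model, rates = best$par,
                 Q = `dimnames<-`(build_Q(best$par, k, model),
                                  list(states, states)),
                 loglik = loglik, k_rates = npar,
                 aic = 2 * npar - 2 * loglik,
                 states = states, tree = tree, spm = spm,
                 root_prior = root_prior,
                 convergence = best$convergence),
            class = "mk_fit")
}

#' Fit ER, SYM and ARD and select by AIC
#'
#' @inheritParams fit_mk
#' @return list: `best` (an `mk_fit`), `fits` (all three), `aic` (named
#'   vector).  Ties within 1e-6 go to the simpler model.
#' @export
fit_mk_models <- function(tree, spm, root_prior = "uniform") {
  models <- c("ER", "SYM", "ARD")
  fits <- lapply(models, function(m) fit_mk(tree, spm, m, root_prior))
  names(fits) <- models
  aic <- vapply(fits, `[[`, 1.0, "aic")
  best <- models[which(aic <= min(aic) + 1e-6)][1L]
  list(best = fits[[best]], fits = fits, aic = aic)
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk fit (", x$model, "): ", length(x$states), " states, logLik = ",
      sprintf("%.4f", x$loglik), ", AIC = ", sprintf("%.4f", x$aic), "\n",
      sep = "")
  invisible(x)
}
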