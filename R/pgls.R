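# Phylogenetic generalized least squares with Brownian-motion covariance.

#' Fit a pGLS regression
#'
#' Generalized least squares of `y ~ x` with error covariance proportional
#' to shared branch lengths under Brownian motion (C_ij = shared
#' root-to-tip path length).  The fit is computed in closed form, which
#' also handles exact (zero-residual) relationships.
#'
#' @param y,x numeric vectors named by tree tip.
#' @param tree an `ape::phylo` covering the names of `y` and `x`.
#' @return list of class `pgls_fit`: `coefficient` (slope), `p_value`
#'   (t-test on the slope), `intercept`, `n`, `sigma2`, `df`.
#' @export
pgls_fit <- function(y, x, tree) {
  if (is.null(names(y)) || is.null(names(x)))
    stop("y and x must be named by tree tip")
  sp <- intersect(tree$tip.label, intersect(names(y), names(x)))
  if (length(sp) < 3L) stop("need at least 3 species for pGLS")
  if (length(sp) < length(tree$tip.label))
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, sp))
  n <- length(sp)
  C <- ape::vcv(tree)[sp, sp]
  Ci <- tryCatch(solve(C), error = function(e)
    stop("pGLS failed (singular covariance): ", conditionMessage(e)))
  X <- cbind(1, as.numeric(x[sp]))
  yy <- as.numeric(y[sp])
  XtCi <- crossprod(X, Ci)
  XtCiX <- XtCi %*% X
  if (abs(det(XtCiX)) < 1e-14 * max(abs(XtCiX))^2)
    stop("pGLS failed: predictor is constant")
  beta <- solve(XtCiX, XtCi %*% yy)
  resid <- yy - X %*% beta
  df <- n - 2L
  sigma2 <- as.numeric(crossprod(resid, Ci %*% resid)) / df
  se <- sqrt(pmax(0, diag(solve(XtCiX)) * sigma2))
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  structure(list(coefficient = beta[2L], p_value = pval[2L],
                 intercept = beta[1L], n = n, sigma2 = sigma2, df = df,
                 model = "Brownian"),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("pGLS (Brownian): slope = %.4g, p = %.4g, n = %d\n",
              x$coefficient, x$p_value, x$n))
  invisible(x)
}
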