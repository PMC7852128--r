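# Beta-binomial maximum likelihood: logit link on the mean proportion mu,
# intra-class correlation rho parameterized on the logit scale so the
# optimizer is unconstrained. With a = mu (1-rho)/rho and b = (1-mu)(1-rho)/rho,
# y ~ BetaBinomial(n, a, b) has mean n mu and variance
# n mu (1-mu) (1 + (n-1) rho).

bb_loglik <- function(y, n, mu, rho) {
  rho <- min(max(rho, 1e-12), 1 - 1e-12)
  s <- (1 - rho) / rho
  a <- mu * s
  b <- (1 - mu) * s
  sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
}

#' Fit one taxon's beta-binomial regression
#'
#' Maximum likelihood fit of overdispersed proportions `y/n` (taxon count
#' over library depth): `logit(mu) = X beta` with intra-class correlation
#' `rho`, optimized jointly over `(beta, logit(rho))` by BFGS from a
#' binomial-GLM start. As `rho -> 0` the model collapses to the plain
#' binomial GLM. The covariance of `beta` is the inverse observed
#' information (beta block of the inverse numerical Hessian). Failures are
#' flagged on the returned object, not raised.
#'
#' @param y Taxon counts, `0 <= y <= n`.
#' @param n Library depths.
#' @param X Design matrix (with intercept column).
#' @param offset Optional per-observation term added to the linear
#'   predictor (used internally when profiling a fixed coefficient).
#' @param control List overriding `max_iter` (BFGS iteration cap, default
#'   200).
#' @return A `taxa_fit` object; `dispersion` holds `rho`.
#' @export
fit_bb <- function(y, n, X, offset = NULL, control = list()) {
  ctl <- modifyList(list(max_iter = 200), control)
  X <- as.matrix(X)
  if (is.null(offset)) offset <- rep(0, length(y))
  if (any(y < 0)) stop("fit_bb: negative counts")
  if (any(y > n)) stop("fit_bb: y > n")
  if (length(y) != nrow(X) || length(n) != length(y))
    stop("fit_bb: dimension mismatch")
  taxon <- attr(y, "taxon") %||% ""
  if (qr(X)$rank < ncol(X))
    return(new_taxa_fit(taxon, family = "betabin", n_obs = length(y),
                        reason = "rank-deficient"))
  if (all(y == 0) || all(y == n))
    return(new_taxa_fit(taxon, family = "betabin", n_obs = length(y),
                        reason = "degenerate response"))

  start_glm <- suppressWarnings(
    glm.fit(X, cbind(y, n - y), family = binomial(), offset = offset))
  start <- c(start_glm$coefficients, qlogis(0.05))
  if (anyNA(start))
    return(new_taxa_fit(taxon, family = "betabin", n_obs = length(y),
                        reason = "bad start"))
  p_beta <- seq_len(ncol(X))
  nll <- function(par) {
    eta <- drop(X %*% par[p_beta]) + offset
    mu <- plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ll <- bb_loglik(y, n, mu, plogis(par[length(par)]))
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- tryCatch(
    optim(start, nll, method = "BFGS",
          control = list(maxit = ctl$max_iter, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10)
    return(new_taxa_fit(taxon, family = "betabin", n_obs = length(y),
                        reason = "diverged"))
  beta <- opt$par[p_beta]
  names(beta) <- colnames(X)
  rho <- plogis(opt$par[length(opt$par)])
  H <- tryCatch(optimHess(opt$par, nll), error = function(e) NULL)
  covb <- NULL
  if (!is.null(H)) {
    Vi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vi)) {
      V <- Vi[p_beta, p_beta, drop = FALSE]
      if (all(is.finite(V)) && all(diag(V) > 0)) {
        dimnames(V) <- list(names(beta), names(beta))
        covb <- V
      }
    }
  }
  converged <- opt$convergence == 0 && !is.null(covb)
  new_taxa_fit(taxon, coefs = beta,
               cov = covb %||% matrix(NA_real_, ncol(X), ncol(X)),
               dispersion = rho, loglik = -opt$value,
               converged = converged, n_obs = length(y), family = "betabin",
               reason = if (converged) NULL else "no optimum")
}
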