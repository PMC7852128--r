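# Negative binomial (NB2) maximum likelihood with log link.
#
# Alternates iteratively reweighted least squares for beta at fixed theta
# with Newton steps for theta on the profile likelihood, the classic
# score-equation scheme for this model. Variance of the response is
# mu + mu^2/theta.

nb_loglik <- function(y, mu, theta) {
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta) - theta * log(theta + mu) +
        y * log(mu) - y * log(theta + mu))
}

# One IRLS pass for beta at fixed theta (log link, NB2 weights).
nb_irls <- function(y, X, offset, theta, beta, max_it = 25, tol = 1e-10) {
  for (it in seq_len(max_it)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -500), 500)
    mu <- exp(eta)
    w <- mu / (1 + mu / theta)           # 1/(V(mu) g'(mu)^2)
    z <- (eta - offset) + (y - mu) / mu  # working response
    bad <- !is.finite(w) | !is.finite(z)
    w[bad] <- 0
    z[bad] <- 0
    if (all(w == 0)) return(NULL)
    fit <- lm.wfit(X, z, w)
    new_beta <- fit$coefficients
    if (anyNA(new_beta) || any(!is.finite(new_beta))) return(NULL)
    if (max(abs(new_beta - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  beta
}

# Newton update for log(theta) holding mu fixed, safeguarded: the step is
# kept only if it improves the profile log-likelihood, otherwise a Brent
# 1-D maximization over the admissible range takes over.
nb_theta_step <- function(y, mu, ltheta) {
  bounds <- log(c(1e-4, 1e6))
  theta <- exp(ltheta)
  score <- sum(digamma(y + theta) - digamma(theta) + log(theta) + 1 -
                 log(theta + mu) - (y + theta) / (theta + mu)) * theta
  hess_t <- sum(trigamma(y + theta) - trigamma(theta) + 1 / theta -
                  2 / (theta + mu) + (y + theta) / (theta + mu)^2)
  hess <- hess_t * theta^2 + score  # d2/dltheta2 via chain rule
  cand <- if (is.finite(hess) && hess < 0 && is.finite(score))
    min(max(ltheta - score / hess, bounds[1]), bounds[2]) else NA_real_
  ll_cur <- nb_loglik(y, mu, theta)
  if (!is.na(cand)) {
    ll_cand <- nb_loglik(y, mu, exp(cand))
    if (is.finite(ll_cand) && ll_cand >= ll_cur) return(cand)
  }
  optimize(function(lt) nb_loglik(y, mu, exp(lt)), bounds,
           maximum = TRUE, tol = 1e-8)$maximum
}

new_taxa_fit <- function(taxon, coefs = NULL, cov = NULL, dispersion = NA_real_,
                         loglik = NA_real_, converged = FALSE, n_obs = NA_integer_,
                         family = NA_character_, reason = NULL) {
  structure(list(taxon = taxon, coefficients = coefs, cov = cov,
                 dispersion = dispersion, loglik = loglik,
                 converged = converged, n_obs = n_obs, family = family,
                 reason = reason),
            class = "taxa_fit")
}

#' @export
print.taxa_fit <- function(x, ...) {
  cat("<taxa_fit> ", x$taxon, " [", x$family, "] ",
      if (x$converged) "converged" else paste0("NOT converged (", x$reason, ")"),
      "\n", sep = "")
  if (!is.null(x$coefficients)) print(x$coefficients)
  invisible(x)
}

#' Fit one taxon's negative binomial (NB2) regression
#'
#' Maximum likelihood fit of `y ~ NB2(mu, theta)` with `log(mu) = X beta +
#' offset` and variance `mu + mu^2/theta`. Estimation alternates weighted
#' least squares for `beta` with Newton steps for `log(theta)` until the
#' relative log-likelihood change falls below `tol`; `theta` is kept in
#' `[1e-4, 1e6]`. The reported covariance of `beta` is the inverse observed
#' information (numerical Hessian of the negative log-likelihood over
#' `(beta, log theta)` at the optimum, `beta` block). Non-convergence —
#' iteration cap, divergence, an all-zero response, or a rank-deficient
#' design — is flagged on the returned object, not raised, because failed
#' taxa flow to the rank-based fallback tests.
#'
#' @param y Non-negative integer response (one taxon's counts).
#' @param X Design matrix (with intercept column).
#' @param offset Per-observation log-depth offset, or `NULL` for none.
#' @param control List overriding `tol` (default `1e-8`) and `max_iter`
#'   (default 50 outer iterations).
#' @return A `taxa_fit` object: `coefficients`, `cov`, `dispersion`
#'   (`theta`), `loglik`, `converged`, `n_obs`.
#' @export
fit_nb <- function(y, X, offset = NULL, control = list()) {
  ctl <- modifyList(list(tol = 1e-8, max_iter = 50), control)
  X <- as.matrix(X)
  if (any(y < 0)) stop("fit_nb: negative counts")
  if (length(y) != nrow(X)) stop("fit_nb: length(y) != nrow(X)")
  if (is.null(offset)) offset <- rep(0, length(y))
  taxon <- attr(y, "taxon") %||% ""
  if (qr(X)$rank < ncol(X))
    return(new_taxa_fit(taxon, family = "negbin", n_obs = length(y),
                        reason = "rank-deficient"))
  if (all(y == 0))
    return(new_taxa_fit(taxon, family = "negbin", n_obs = length(y),
                        reason = "all-zero response"))

  # moment start: mean rate on the intercept column if there is one, theta
  # from the overdispersion of the marginal counts
  mu0 <- max(mean(y / exp(pmin(pmax(offset, -500), 500))), 1e-8)
  beta <- rep(0, ncol(X))
  icol <- which(apply(X, 2L, function(cl) all(cl == 1)))[1]
  if (!is.na(icol)) beta[icol] <- log(mu0)
  mu <- exp(drop(X %*% beta) + offset)
  v <- var(y)
  ltheta <- log(min(max(if (v > mean(y)) mean(mu)^2 / (v - mean(y)) else 10,
                        1e-2), 1e4))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(ctl$max_iter)) {
    beta_new <- nb_irls(y, X, offset, exp(ltheta), beta)
    if (is.null(beta_new))
      return(new_taxa_fit(taxon, family = "negbin", n_obs = length(y),
                          reason = "diverged"))
    beta <- beta_new
    mu <- exp(drop(X %*% beta) + offset)
    ltheta <- nb_theta_step(y, mu, ltheta)
    ll <- nb_loglik(y, mu, exp(ltheta))
    if (!is.finite(ll))
      return(new_taxa_fit(taxon, family = "negbin", n_obs = length(y),
                          reason = "diverged"))
    if (abs(ll - ll_old) < ctl$tol * (abs(ll) + ctl$tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  theta <- exp(ltheta)
  names(beta) <- colnames(X)
  covb <- nb_cov(y, X, offset, beta, ltheta)
  if (is.null(covb)) {
    converged <- FALSE
    reason <- "singular information"
    covb <- matrix(NA_real_, ncol(X), ncol(X))
  } else reason <- if (converged) NULL else "iteration limit"
  new_taxa_fit(taxon, coefs = beta, cov = covb, dispersion = theta,
               loglik = nb_loglik(y, exp(drop(X %*% beta) + offset), theta),
               converged = converged, n_obs = length(y), family = "negbin",
               reason = reason)
}

# Observed information of (beta, log theta); returns the beta block of the
# inverse, with coefficient dimnames.
nb_cov <- function(y, X, offset, beta, ltheta) {
  par <- c(beta, ltheta)
  nll <- function(p) {
    mu <- exp(drop(X %*% p[seq_along(beta)]) + offset)
    -nb_loglik(y, mu, exp(p[length(p)]))
  }
  H <- tryCatch(optimHess(par, nll), error = function(e) NULL)
  if (is.null(H)) return(NULL)
  Vi <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(Vi)) return(NULL)
  V <- Vi[seq_along(beta), seq_along(beta), drop = FALSE]
  if (any(!is.finite(V)) || any(diag(V) <= 0)) return(NULL)
  dimnames(V) <- list(names(beta), names(beta))
  V
}

`%||%` <- function(a, b) if (is.null(a)) b else a
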