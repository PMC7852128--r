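#' Fit one regression per taxon of an OTU table
#'
#' Builds a single design matrix from the model formula (treatment coding;
#' a factor's first level is the reference) and fits every taxon of the
#' table with the chosen family: negative binomial on counts with an
#' optional `log(depth)` offset to account for the compositional denominator
#' ([fit_nb()]), or beta-binomial on count/depth proportions ([fit_bb()]).
#' Libraries with missing covariate values are dropped with a warning.
#' Taxa whose fits do not converge are collected separately — they are data
#' for the rank-based fallback tests ([rank_taxa_test()],
#' [presence_chisq()]), not an error.
#'
#' @param micro_set A `micro_set`.
#' @param table Table name.
#' @param formula One-sided model formula of clinical covariates, e.g.
#'   `~ Group * Age`.
#' @param family `"negbin"` or `"betabin"`.
#' @param offset For `"negbin"`: include `log(depth)` as the model offset
#'   (default `TRUE`). Ignored for `"betabin"`, which models the proportion
#'   directly.
#' @param control Passed to the per-taxon fitter.
#' @return A `taxa_models` object: `fits` (converged `taxa_fit`s), `failed`
#'   (non-converged), plus the design information needed by
#'   [covariate_lrt()], [profile_ci()], [estimate_table()] and
#'   [nb_bars_data()].
#' @export
taxa_models <- function(micro_set, table, formula, family = c("negbin", "betabin"),
                        offset = TRUE, control = list()) {
  family <- match.arg(family)
  stopifnot(inherits(micro_set, "micro_set"))
  formula <- as.formula(formula)
  lib_data <- ms_lib_data(micro_set, table)
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(lib_data))
  if (length(missing_vars))
    stop("covariate(s) not in micro_set: ", paste(missing_vars, collapse = ", "))
  ok <- complete.cases(lib_data[vars])
  if (!all(ok)) {
    warning(sum(!ok), " librar", if (sum(!ok) == 1) "y" else "ies",
            " dropped for missing covariates: ",
            paste(lib_data$Lib[!ok], collapse = ", "))
    lib_data <- lib_data[ok, , drop = FALSE]
  }
  if (nrow(lib_data) < 2L) stop("fewer than 2 libraries with complete covariates")
  mf <- model.frame(formula, data = lib_data)
  trms <- attr(mf, "terms")
  X <- model.matrix(trms, mf)
  y_mat <- ms_matrix(micro_set, table, "cts")[lib_data$Lib, , drop = FALSE]
  depth <- rowSums(y_mat)
  off <- if (family == "negbin" && offset) log(depth) else NULL

  fits <- vector("list", ncol(y_mat))
  names(fits) <- colnames(y_mat)
  for (tx in colnames(y_mat)) {
    y <- y_mat[, tx]
    attr(y, "taxon") <- tx
    fits[[tx]] <- if (family == "negbin") {
      fit_nb(y, X, offset = off, control = control)
    } else {
      fit_bb(y, depth, X, control = control)
    }
  }
  conv <- vapply(fits, function(f) f$converged, logical(1))
  if (any(!conv))
    mt_log("taxa_models [", table, ", ", family, "]: ", sum(!conv),
           " taxa did not converge: ", paste(names(fits)[!conv], collapse = ", "))
  structure(
    list(table = as.character(table), formula = formula, family = family,
         offset = !is.null(off),
         fits = fits[conv], failed = fits[!conv],
         X = X, terms = trms, xlevels = stats::.getXlevels(trms, mf),
         lib_data = lib_data, y_mat = y_mat, depth = depth,
         log_offset = off),
    class = "taxa_models")
}

#' @rdname taxa_models
#' @param ... Passed on to [taxa_models()].
#' @export
nb_mods <- function(micro_set, table, formula, offset = TRUE, ...) {
  taxa_models(micro_set, table, formula, family = "negbin", offset = offset, ...)
}

#' @rdname taxa_models
#' @export
bb_mods <- function(micro_set, table, formula, ...) {
  taxa_models(micro_set, table, formula, family = "betabin", ...)
}

#' @export
print.taxa_models <- function(x, ...) {
  cat("<taxa_models> table=", x$table, ", family=", x$family, ", formula=",
      deparse(x$formula), "\n  ", length(x$fits), " converged, ",
      length(x$failed), " failed",
      if (length(x$failed)) paste0(" (", paste(names(x$failed), collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Taxa that failed to converge in a model set
#' @param models A `taxa_models` object.
#' @return Character vector of taxon labels.
#' @export
failed_taxa <- function(models) names(models$failed)

# Refit one taxon with a modified design; used by LRT and profiling.
refit_taxon <- function(models, taxon, X, extra_offset = 0) {
  y <- models$y_mat[, taxon]
  if (models$family == "negbin") {
    off <- (models$log_offset %||% rep(0, length(y))) + extra_offset
    if (ncol(X) == 0L) {
      mu <- exp(off)
      opt <- optimize(function(lt) nb_loglik(y, mu, exp(lt)),
                      c(log(1e-4), log(1e6)), maximum = TRUE)
      return(list(loglik = opt$objective, converged = TRUE))
    }
    f <- fit_nb(y, X, offset = off)
  } else {
    if (ncol(X) == 0L) {
      mu <- pmin(pmax(plogis(extra_offset + rep(0, length(y))), 1e-12), 1 - 1e-12)
      opt <- optimize(function(lr) bb_loglik(y, models$depth, mu, plogis(lr)),
                      c(-30, 30), maximum = TRUE)
      return(list(loglik = opt$objective, converged = TRUE))
    }
    f <- fit_bb(y, models$depth, X, offset = rep(0, length(y)) + extra_offset)
  }
  list(loglik = f$loglik, converged = f$converged)
}

#' Likelihood ratio test for an entire covariate
#'
#' For each converged taxon, refits the model with the named covariate — and
#' every interaction involving it — removed, and compares twice the
#' log-likelihood difference to a chi-square with df equal to the number of
#' design columns removed. This is the whole-covariate test reported
#' alongside the per-coefficient Wald tests in [taxa_summary()], analogous
#' to an F-test for a multi-level factor.
#'
#' @param models A `taxa_models` object.
#' @param term A covariate name appearing in the model formula.
#' @return A tibble of `Taxa`, `term`, `df`, `lr`, `p` (NA with a reason
#'   when the reduced fit fails).
#' @export
covariate_lrt <- function(models, term) {
  labels <- attr(models$terms, "term.labels")
  if (!term %in% all.vars(models$formula))
    stop("term '", term, "' not in the model formula")
  involves <- vapply(strsplit(labels, ":", fixed = TRUE),
                     function(parts) term %in% parts, logical(1))
  keep_labels <- labels[!involves]
  asgn <- attr(models$X, "assign")
  keep_cols <- asgn %in% c(0L, which(!involves))
  df <- sum(!keep_cols)
  if (df == 0L) stop("term '", term, "' contributes no design columns")
  Xr <- models$X[, keep_cols, drop = FALSE]
  rows <- lapply(names(models$fits), function(tx) {
    full <- models$fits[[tx]]
    red <- refit_taxon(models, tx, Xr)
    if (!isTRUE(red$converged) || !is.finite(red$loglik))
      return(tibble::tibble(Taxa = tx, term = term, df = df,
                            lr = NA_real_, p = NA_real_))
    lr <- max(2 * (full$loglik - red$loglik), 0)
    tibble::tibble(Taxa = tx, term = term, df = df, lr = lr,
                   p = pchisq(lr, df = df, lower.tail = FALSE))
  })
  dplyr::bind_rows(rows)
}

#' Profile-likelihood confidence intervals for model coefficients
#'
#' For each coefficient of each converged fit, finds the values where twice
#' the drop from the maximized log-likelihood — re-maximizing all other
#' parameters, including the dispersion — equals the chi-square(1) quantile
#' at `level`. Roots are bracketed starting from the Wald interval and
#' expanded outward; if profiling fails on a side, the Wald limit is used
#' and the row is marked `method = "wald"` with a logged note. The interval
#' always contains the MLE.
#'
#' @param models A `taxa_models` object.
#' @param level Coverage probability (default 0.95).
#' @param taxa Optional subset of taxa.
#' @return A tibble of `Taxa`, `Coefficient`, `Estimate`, `ci_low`,
#'   `ci_high`, `method`.
#' @export
profile_ci <- function(models, level = 0.95, taxa = NULL) {
  crit <- qchisq(level, df = 1)
  taxa <- taxa %||% names(models$fits)
  rows <- list()
  for (tx in taxa) {
    fit <- models$fits[[tx]]
    if (is.null(fit)) next
    se <- sqrt(diag(fit$cov))
    for (j in seq_along(fit$coefficients)) {
      nm <- names(fit$coefficients)[j]
      est <- fit$coefficients[j]
      Xr <- models$X[, -j, drop = FALSE]
      pll <- function(bj)
        refit_taxon(models, tx, Xr, extra_offset = models$X[, j] * bj)$loglik
      dev <- function(bj) 2 * (fit$loglik - pll(bj)) - crit
      lim <- function(side) {
        w <- se[j]
        for (mult in c(1.2, 2, 4, 8, 16)) {
          cand <- est + side * qnorm(1 - (1 - level) / 2) * w * mult
          val <- tryCatch(dev(cand), error = function(e) NA_real_)
          if (is.na(val)) return(NA_real_)
          if (val > 0) {
            r <- tryCatch(
              uniroot(dev, sort(c(est, cand)), tol = 1e-6)$root,
              error = function(e) NA_real_)
            return(r)
          }
        }
        NA_real_
      }
      lo <- lim(-1)
      hi <- lim(+1)
      meth <- "profile"
      zq <- qnorm(1 - (1 - level) / 2)
      if (is.na(lo) || is.na(hi)) {
        mt_log("profile_ci: Wald fallback for ", tx, " / ", nm)
        if (is.na(lo)) lo <- est - zq * se[j]
        if (is.na(hi)) hi <- est + zq * se[j]
        meth <- "wald"
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        Taxa = tx, Coefficient = nm, Estimate = unname(est),
        ci_low = lo, ci_high = hi, method = meth)
    }
  }
  dplyr::bind_rows(rows)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), returned in the input
#' order. A thin validating wrapper around [stats::p.adjust()].
#'
#' @param p Vector of p-values in \[0, 1\] (NAs are passed through).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Model summary table (one row per taxon and coefficient)
#'
#' The automated per-model summary: coefficient estimates,
#' profile-likelihood confidence intervals, Wald Z statistics and p-values,
#' FDR-adjusted p-values (pooled across taxa within each coefficient), and
#' the whole-covariate likelihood-ratio p-value repeated across that
#' covariate's coefficients.
#'
#' @param models A `taxa_models` object.
#' @param level Confidence level (default 0.95).
#' @param ci `"profile"` (default) or `"wald"` intervals.
#' @return A tibble of `Taxa`, `Coefficient`, `Estimate`, `ci_low`,
#'   `ci_high`, `z`, `p`, `fdr_p`, `lrt_term`, `lrt_p`.
#' @export
taxa_summary <- function(models, level = 0.95, ci = c("profile", "wald")) {
  ci <- match.arg(ci)
  if (!length(models$fits)) stop("no converged fits to summarize")
  zq <- qnorm(1 - (1 - level) / 2)
  base <- dplyr::bind_rows(lapply(names(models$fits), function(tx) {
    fit <- models$fits[[tx]]
    se <- sqrt(diag(fit$cov))
    tibble::tibble(Taxa = tx, Coefficient = names(fit$coefficients),
                   Estimate = unname(fit$coefficients), se = unname(se))
  }))
  base$z <- base$Estimate / base$se
  base$p <- 2 * pnorm(-abs(base$z))
  base <- base |>
    dplyr::group_by(.data$Coefficient) |>
    dplyr::mutate(fdr_p = bh_adjust(.data$p)) |>
    dplyr::ungroup()
  if (ci == "profile") {
    pci <- profile_ci(models, level = level)
    base <- dplyr::left_join(base,
                             pci[c("Taxa", "Coefficient", "ci_low", "ci_high")],
                             by = c("Taxa", "Coefficient"))
  } else {
    base$ci_low <- base$Estimate - zq * base$se
    base$ci_high <- base$Estimate + zq * base$se
  }
  # whole-covariate LRT, mapped back to each coefficient via the assign index
  labels <- attr(models$terms, "term.labels")
  asgn <- attr(models$X, "assign")
  coef_term <- function(nm) {
    j <- match(nm, colnames(models$X))
    if (asgn[j] == 0L) return(NA_character_)
    parts <- strsplit(labels[asgn[j]], ":", fixed = TRUE)[[1L]]
    parts[1L]  # leading covariate of the term
  }
  base$lrt_term <- vapply(base$Coefficient, coef_term, character(1))
  lrts <- lapply(unique(na.omit(base$lrt_term)), function(tm)
    dplyr::mutate(covariate_lrt(models, tm), lrt_term = tm))
  lrt_tbl <- dplyr::bind_rows(lrts)
  if (nrow(lrt_tbl)) {
    base <- dplyr::left_join(
      base, dplyr::select(lrt_tbl, "Taxa", "lrt_term", lrt_p = "p"),
      by = c("Taxa", "lrt_term"))
  } else base$lrt_p <- NA_real_
  dplyr::select(base, "Taxa", "Coefficient", "Estimate", "ci_low", "ci_high",
                "z", "p", "fdr_p", "lrt_term", "lrt_p")
}

#' Exponentiated estimate table with interaction contrasts
#'
#' One row per taxon and coefficient: the rate ratio (negative binomial) or
#' odds ratio (beta-binomial) `exp(beta)`, its Wald confidence interval, the
#' Z statistic, and the FDR-adjusted p-value pooled across taxa within each
#' coefficient label. When the model contains interactions, an additional
#' contrast row is emitted for every (main effect, interaction) pair: the
#' main-effect and interaction coefficients are summed before
#' exponentiation, with variance `var1 + var2 + 2 cov`, giving e.g. the
#' group effect within a stratum.
#'
#' @param models A `taxa_models` object.
#' @param level Confidence level (default 0.95).
#' @return A tibble of `Taxa`, `Coefficient`, `ratio`, `ci_low`, `ci_high`,
#'   `z`, `fdr_p`.
#' @export
estimate_table <- function(models, level = 0.95) {
  if (!length(models$fits)) stop("no converged fits")
  zq <- qnorm(1 - (1 - level) / 2)
  one_taxon <- function(tx) {
    fit <- models$fits[[tx]]
    cf <- fit$coefficients
    V <- fit$cov
    plain <- tibble::tibble(Taxa = tx, Coefficient = names(cf),
                            est = unname(cf), var = unname(diag(V)))
    inter <- names(cf)[grepl(":", names(cf), fixed = TRUE)]
    extra <- list()
    for (ic in inter) {
      parts <- strsplit(ic, ":", fixed = TRUE)[[1L]]
      for (mn in parts) {
        if (!mn %in% names(cf)) next
        extra[[length(extra) + 1L]] <- tibble::tibble(
          Taxa = tx, Coefficient = paste0(mn, " + ", ic),
          est = unname(cf[mn] + cf[ic]),
          var = unname(V[mn, mn] + V[ic, ic] + 2 * V[mn, ic]))
      }
    }
    dplyr::bind_rows(c(list(plain), extra))
  }
  tab <- dplyr::bind_rows(lapply(names(models$fits), one_taxon))
  tab$se <- sqrt(tab$var)
  tab$ratio <- exp(tab$est)
  tab$ci_low <- exp(tab$est - zq * tab$se)
  tab$ci_high <- exp(tab$est + zq * tab$se)
  tab$z <- tab$est / tab$se
  tab <- tab |>
    dplyr::group_by(.data$Coefficient) |>
    dplyr::mutate(fdr_p = bh_adjust(2 * pnorm(-abs(.data$z)))) |>
    dplyr::ungroup()
  dplyr::select(tab, "Taxa", "Coefficient", "ratio", "ci_low", "ci_high",
                "z", "fdr_p")
}
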