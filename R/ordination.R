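new_ordination <- function(scores, explained, method, loadings = NULL,
                           negative_eig = numeric()) {
  structure(list(scores = scores, loadings = loadings, explained = explained,
                 method = method, axis_count = ncol(scores),
                 negative_eig = negative_eig),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("<ordination> method=", x$method, ", ", nrow(x$scores), " samples, ",
      x$axis_count, " axes; explained: ",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 3)),
            collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

# Deterministic sign convention: on every axis the loading (or score, when no
# loadings exist) of largest magnitude is made positive.
fix_signs <- function(scores, loadings = NULL) {
  ref <- if (is.null(loadings)) scores else loadings
  for (k in seq_len(ncol(scores))) {
    j <- which.max(abs(ref[, k]))
    if (ref[j, k] < 0) {
      scores[, k] <- -scores[, k]
      if (!is.null(loadings)) loadings[, k] <- -loadings[, k]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal component analysis of CLR-transformed counts
#'
#' Builds the libraries x taxa matrix of CLR values for one table, centers
#' each taxon column, and decomposes it by SVD. Scores are the left singular
#' vectors scaled by the singular values; the variance explained by axis
#' `i` is `sigma_i^2 / sum(sigma^2)`.
#'
#' @param micro_set A `micro_set`.
#' @param table Table name.
#' @return An `ordination` object with per-library `scores` (rownamed by
#'   library ID), per-taxon `loadings`, and `explained` fractions.
#' @export
pca_clr <- function(micro_set, table) {
  m <- ms_matrix(micro_set, table, "clr")
  if (nrow(m) < 2L || ncol(m) < 2L) stop("pca_clr needs >= 2 libraries and >= 2 taxa")
  pca_matrix(m)
}

pca_matrix <- function(m) {
  mc <- scale(m, center = TRUE, scale = FALSE)
  if (sum(mc^2) < 1e-12) stop("pca: matrix has no variance")
  sv <- svd(mc)
  keep <- sv$d > 1e-10 * sv$d[1L]
  d <- sv$d[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, nrow = length(d))
  loadings <- sv$v[, keep, drop = FALSE]
  rownames(scores) <- rownames(m)
  rownames(loadings) <- colnames(m)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(sum(keep)))
  fx <- fix_signs(scores, loadings)
  new_ordination(fx$scores, explained = d^2 / sum(sv$d^2), method = "pca",
                 loadings = fx$loadings)
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower-centers `-(1/2) D^2`, eigendecomposes, and keeps the axes with
#' positive eigenvalues (relative tolerance `1e-10`). Scores are
#' eigenvectors scaled by the square root of their eigenvalues; `explained`
#' is computed over the positive eigenvalues only, and any negative
#' eigenvalues (from non-Euclidean dissimilarities such as Bray-Curtis) are
#' reported in the `negative_eig` diagnostics field, not corrected.
#'
#' @param dist Symmetric dissimilarity matrix (e.g. [beta_dissimilarity()]).
#' @return An `ordination` object (no loadings). An all-zero dissimilarity
#'   matrix yields zero retained axes.
#' @export
pcoa <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 3L) stop("pcoa needs >= 3 samples")
  ctr <- diag(n) - matrix(1 / n, n, n)
  gmat <- ctr %*% (-0.5 * d^2) %*% ctr
  ev <- eigen((gmat + t(gmat)) / 2, symmetric = TRUE)
  tol <- 1e-10 * max(abs(ev$values), 1e-300)
  keep <- ev$values > tol
  lambda <- ev$values[keep]
  scores <- ev$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(lambda), nrow = length(lambda))
  rownames(scores) <- rownames(d)
  if (ncol(scores) > 0) colnames(scores) <- paste0("PCo", seq_len(ncol(scores)))
  scores <- fix_signs(scores)$scores
  new_ordination(scores, explained = if (length(lambda)) lambda / sum(lambda)
                 else numeric(),
                 method = "pcoa", negative_eig = ev$values[ev$values < -tol])
}

#' Three-mode ordination of repeated-measures microbiome data
#'
#' Ordains a subjects x taxa x time array by collapsing the time mode onto a
#' single set of axes, so each subject's trajectory can be drawn in one
#' score space. Only subjects observed at every time point are used
#' (complete cases); excluded subjects are logged.
#'
#' For `method = "pca"` the array of CLR values is unfolded by stacking the
#' time slices along the sample mode into a (subject x time) x taxa matrix
#' sharing one set of taxa loadings, then decomposed as in [pca_clr()]. For
#' `method = "pcoa"` the chosen dissimilarity is computed among all
#' (subject, time) samples; each time slice's sub-matrix is Gower-centered,
#' the centered matrices are averaged across time to fix common axes, and
#' every sample is projected onto those axes.
#'
#' With a single time point both methods reduce to their standard
#' counterparts.
#'
#' @param micro_set A `micro_set`.
#' @param table Table name.
#' @param subject,time Clinical column names identifying the subject and the
#'   time point of each library.
#' @param method `"pca"` or `"pcoa"`.
#' @param dist_method Dissimilarity for `method = "pcoa"` (see
#'   [beta_dissimilarity()]); default `"bray"`.
#' @return An `ordination` object whose `scores` carry a `sample_info`
#'   attribute: a tibble of `Lib`, subject and time for each score row.
#' @export
three_mode_ordinate <- function(micro_set, table, subject, time,
                                method = c("pca", "pcoa"),
                                dist_method = "bray") {
  method <- match.arg(method)
  stopifnot(inherits(micro_set, "micro_set"))
  lib_data <- ms_table(micro_set, table) |>
    dplyr::distinct(.data$Lib, .keep_all = TRUE)
  for (col in c(subject, time))
    if (!col %in% names(lib_data)) stop("column '", col, "' not in micro_set")
  info <- tibble::tibble(Lib = lib_data$Lib,
                         subject = as.character(lib_data[[subject]]),
                         time = as.character(lib_data[[time]]))
  all_times <- unique(info$time)
  by_subj <- split(info$time, info$subject)
  complete <- names(by_subj)[vapply(by_subj, function(tt)
    all(all_times %in% tt), logical(1))]
  dropped <- setdiff(names(by_subj), complete)
  if (length(dropped))
    mt_log("three_mode_ordinate: excluding ", length(dropped),
           " incomplete subject(s): ", paste(dropped, collapse = ", "))
  if (length(complete) < 2L) stop("need >= 2 complete-case subjects")
  info <- info[info$subject %in% complete, , drop = FALSE]
  info <- info[order(match(info$time, all_times),
                     match(info$subject, complete)), , drop = FALSE]

  if (method == "pca") {
    m <- ms_matrix(micro_set, table, "clr")[info$Lib, , drop = FALSE]
    ord <- pca_matrix(m)
  } else {
    d_all <- beta_dissimilarity(micro_set, table, dist_method)
    d_all <- d_all[info$Lib, info$Lib, drop = FALSE]
    ns <- length(complete)
    slices <- lapply(all_times, function(tt) which(info$time == tt))
    ctr <- diag(ns) - matrix(1 / ns, ns, ns)
    gs <- lapply(slices, function(ix) {
      ds <- d_all[ix, ix, drop = FALSE]
      ctr %*% (-0.5 * ds^2) %*% ctr
    })
    gbar <- Reduce(`+`, gs) / length(gs)
    ev <- eigen((gbar + t(gbar)) / 2, symmetric = TRUE)
    tol <- 1e-10 * max(abs(ev$values), 1e-300)
    keep <- ev$values > tol
    lambda <- ev$values[keep]
    if (!length(lambda)) stop("three-mode pcoa: no positive axes")
    v <- ev$vectors[, keep, drop = FALSE]
    # project each time slice's centered Gower matrix onto the common axes
    scores <- matrix(NA_real_, nrow = nrow(info), ncol = length(lambda),
                     dimnames = list(info$Lib, paste0("PCo", seq_along(lambda))))
    for (s in seq_along(slices)) {
      scores[slices[[s]], ] <- gs[[s]] %*% v %*%
        diag(1 / sqrt(lambda), nrow = length(lambda))
    }
    scores <- fix_signs(scores)$scores
    ord <- new_ordination(scores, explained = lambda / sum(lambda),
                          method = "pcoa",
                          negative_eig = ev$values[ev$values < -tol])
  }
  attr(ord$scores, "sample_info") <- info
  ord
}

#' Normal confidence ellipses for 2-D ordination scores
#'
#' For each group with at least 3 points, returns the boundary of the
#' bivariate-normal ellipse defined by the group mean and covariance scaled
#' by the chi-square quantile with 2 df at `level`, as a closed 100-point
#' path. Groups with fewer than 3 points are skipped with a warning.
#'
#' @param scores Matrix or data frame with >= 2 columns of coordinates
#'   (first two used).
#' @param groups Group label per row.
#' @param level Coverage probability (default 0.95).
#' @return A tibble of `group`, `x`, `y` tracing one closed path per group.
#' @export
ordination_ellipse <- function(scores, groups, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  xy <- as.matrix(scores)[, 1:2, drop = FALSE]
  stopifnot(nrow(xy) == length(groups))
  r2 <- qchisq(level, df = 2)
  theta <- seq(0, 2 * pi, length.out = 100)
  circle <- cbind(cos(theta), sin(theta))
  paths <- lapply(split(seq_along(groups), groups), function(ix) {
    if (length(ix) < 3L) {
      warning("ellipse skipped for group with < 3 points")
      return(NULL)
    }
    mu <- colMeans(xy[ix, , drop = FALSE])
    sig <- cov(xy[ix, , drop = FALSE])
    ch <- chol(sig * r2)
    pts <- circle %*% ch
    tibble::tibble(x = pts[, 1] + mu[1], y = pts[, 2] + mu[2])
  })
  dplyr::bind_rows(paths[!vapply(paths, is.null, logical(1))], .id = "group")
}
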