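#' Between-library dissimilarity matrix
#'
#' Computes a full symmetric dissimilarity matrix among the libraries of one
#' OTU table. `"bray"` is Bray-Curtis on raw counts and `"jaccard-binary"`
#' is the binary Jaccard dissimilarity on presence/absence, both via
#' [vegan::vegdist()]; `"euclidean-clr"` is the Euclidean (Aitchison)
#' distance between CLR vectors.
#'
#' @param micro_set A `micro_set`.
#' @param table Table name.
#' @param method One of `"bray"`, `"jaccard-binary"`, `"euclidean-clr"`.
#' @return Symmetric numeric matrix with library IDs as dimnames.
#' @export
beta_dissimilarity <- function(micro_set, table,
                               method = c("bray", "jaccard-binary",
                                          "euclidean-clr")) {
  method <- match.arg(method)
  m <- switch(method,
    "bray" = vegan::vegdist(ms_matrix(micro_set, table, "cts"),
                            method = "bray"),
    "jaccard-binary" = vegan::vegdist(ms_matrix(micro_set, table, "bin"),
                                      method = "jaccard", binary = TRUE),
    "euclidean-clr" = stats::dist(ms_matrix(micro_set, table, "clr")))
  if (attr(m, "Size") < 2L) stop("beta_dissimilarity needs >= 2 libraries")
  as.matrix(m)
}

#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Partitions the total sum of squares of the Gower-centered matrix
#' `G = -(1/2) J D^2 J` into between- and within-group components via the
#' group-membership hat matrix, forms the pseudo-F ratio
#' `F = (SSB/(g-1)) / (SSW/(n-g))`, and estimates the p-value by permuting
#' the group labels, using the add-one estimator
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param dist Symmetric dissimilarity matrix with library IDs as dimnames
#'   (e.g. from [beta_dissimilarity()]).
#' @param groups Group labels, one per library, aligned with `dist` (or
#'   named by library ID).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `pseudo_f`, `r2` (SSB/SST), `p`, `n_perm`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0))
    stop("dist must be a symmetric matrix with zero diagonal")
  if (!is.null(names(groups)) && !is.null(rownames(d)))
    groups <- groups[rownames(d)]
  if (length(groups) != n) stop("groups must align with the distance matrix")
  if (anyNA(groups)) stop("groups must not contain NA")
  f <- factor(groups)
  g <- nlevels(f)
  if (g < 2L) stop("permanova needs >= 2 groups")
  if (g >= n) stop("permanova needs within-group residual df (n > #groups)")
  gower <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  gmat <- ctr %*% gower %*% ctr
  sst <- sum(diag(gmat))
  if (sst < 1e-12)  # all points coincide: nothing to partition
    return(tibble::tibble(pseudo_f = 0, r2 = 0, p = 1, n_perm = n_perm))
  pseudo_f_of <- function(fac) {
    x <- model.matrix(~ fac - 1)
    hat <- x %*% solve(crossprod(x), t(x))
    ssb <- sum(hat * gmat)  # tr(H G) = tr(H G H) since H idempotent
    ssw <- sst - ssb
    list(f = (ssb / (g - 1)) / (ssw / (n - g)), r2 = ssb / sst)
  }
  obs <- pseudo_f_of(f)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (pseudo_f_of(f[sample.int(n)])$f >= obs$f - 1e-12) hits <- hits + 1L
  }
  tibble::tibble(pseudo_f = obs$f, r2 = obs$r2,
                 p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}
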