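#' Good's coverage of a sequencing library
#'
#' Estimated probability, in percent, that the next sequenced read belongs
#' to a taxon already observed: `100 * (1 - F1/N)` with `F1` the number of
#' singleton taxa and `N` the total reads.
#'
#' @param counts Count vector of one library.
#' @return Coverage percent in \[0, 100\].
#' @examples
#' good_coverage(c(3, 3, 2, 1, 1))  # 80
#' @export
good_coverage <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n <= 0) stop("good_coverage: library has no reads")
  100 * (1 - sum(counts == 1) / n)
}

#' Alpha diversity indices of one count vector
#'
#' Computes observed richness, the Chao1 richness estimate, Shannon
#' diversity (natural log) and evenness, Simpson diversity (`1 - D`) and
#' evenness (`(1/D)/S_obs`), and Good's coverage. Chao1 uses the classic
#' `S_obs + F1^2/(2 F2)` form, falling back to the bias-corrected
#' `S_obs + F1(F1 - 1)/2` when there are no doubletons. Shannon evenness is
#' defined as 1 for a single-taxon library.
#'
#' @param counts Count vector of one library.
#' @return A one-row tibble with columns `sobs`, `chao1`, `shannon_h`,
#'   `shannon_e`, `simpson_div`, `simpson_e`, `goods`.
#' @examples
#' alpha_indices(c(1, 1, 2, 3, 5))
#' @export
alpha_indices <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n <= 0) stop("alpha_indices: library has no reads")
  obs <- counts[counts > 0]
  sobs <- length(obs)
  f1 <- sum(obs == 1)
  f2 <- sum(obs == 2)
  chao1 <- if (f2 > 0) sobs + f1^2 / (2 * f2) else sobs + f1 * (f1 - 1) / 2
  p <- obs / n
  shannon_h <- -sum(p * log(p))
  shannon_e <- if (sobs > 1) shannon_h / log(sobs) else 1
  d <- sum(p^2)
  tibble::tibble(
    sobs = sobs, chao1 = chao1,
    shannon_h = shannon_h, shannon_e = shannon_e,
    simpson_div = 1 - d, simpson_e = (1 / d) / sobs,
    goods = 100 * (1 - f1 / n))
}

#' Bootstrap-rarefy a library to a fixed depth
#'
#' Draws `depth` reads with replacement from the library's read pool (a
#' multinomial draw with probabilities proportional to the counts), the
#' "bootstrapped" flavor of rarefaction whose repeated draws are averaged by
#' [alpha_div()]. The output always sums exactly to `depth`; taxa with zero
#' counts stay zero.
#'
#' @param counts Count vector of one library.
#' @param depth Target number of reads (>= 1).
#' @param seed Optional integer seed for a reproducible draw.
#' @return Integer vector of rarefied counts, same length as `counts`.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  if (depth < 1) stop("rarefy: depth must be >= 1")
  n <- sum(counts)
  if (n < 1) stop("rarefy: library has no reads")
  if (!is.null(seed)) set.seed(seed)
  as.integer(rmultinom(1L, size = depth, prob = counts / n))
}

#' Bootstrapped-rarefaction alpha diversity for one OTU table
#'
#' Libraries are first gated on the raw (pre-rarefaction) data: any with
#' depth below `min_depth` or Good's coverage below `min_goods` are excluded
#' with a recorded status. Each kept library is then rarefied `iter` times to
#' `min_depth` reads and each index is averaged across the iterations.
#'
#' @param micro_set A `micro_set`.
#' @param table Table name to compute diversity on (use the lowest available
#'   taxonomic rank; coarser ranks bias richness estimates downwards).
#' @param iter Number of bootstrap rarefactions (default 100).
#' @param min_depth Depth gate and rarefaction target, reads (default 10000).
#' @param min_goods Good's-coverage gate, percent (default 90).
#' @param seed Integer seed; the whole table's draw is reproducible.
#' @return A tibble with one row per library: `Lib`, `status` (one of
#'   `"kept"`, `"dropped-low-depth"`, `"dropped-low-coverage"`), raw `depth`
#'   and `goods_raw`, the averaged indices (NA for gated-out libraries), and
#'   the library's clinical covariates.
#' @export
alpha_div <- function(micro_set, table, iter = 100, min_depth = 10000,
                      min_goods = 90, seed = NULL) {
  stopifnot(inherits(micro_set, "micro_set"))
  if (iter < 1) stop("iter must be >= 1")
  cts <- ms_matrix(micro_set, table, "cts")  # libs x taxa
  depth <- rowSums(cts)
  goods_raw <- apply(cts, 1L, good_coverage)
  status <- dplyr::case_when(
    depth < min_depth ~ "dropped-low-depth",
    goods_raw < min_goods ~ "dropped-low-coverage",
    TRUE ~ "kept")
  if (!any(status == "kept"))
    stop("alpha_div: no library passes the depth/coverage gates")
  for (s in c("dropped-low-depth", "dropped-low-coverage")) {
    if (any(status == s))
      mt_log("alpha_div [", table, "]: ", s, ": ",
             paste(rownames(cts)[status == s], collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  idx_cols <- c("sobs", "chao1", "shannon_h", "shannon_e",
                "simpson_div", "simpson_e", "goods")
  res <- matrix(NA_real_, nrow = nrow(cts), ncol = length(idx_cols),
                dimnames = list(rownames(cts), idx_cols))
  for (i in which(status == "kept")) {
    acc <- matrix(NA_real_, nrow = iter, ncol = length(idx_cols))
    for (b in seq_len(iter)) {
      boot <- rarefy(cts[i, ], depth = min_depth)
      acc[b, ] <- as.numeric(alpha_indices(boot)[1L, idx_cols])
    }
    res[i, ] <- colMeans(acc)
  }
  out <- tibble::tibble(Lib = rownames(cts), Table = as.character(table),
                        status = status, depth = depth, goods_raw = goods_raw)
  out <- dplyr::bind_cols(out, tibble::as_tibble(res))
  dplyr::left_join(out, ms_lib_data(micro_set, table), by = "Lib")
}
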