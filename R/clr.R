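#' Centered log-ratio transform with a 1/depth pseudocount
#'
#' Maps one library's full count vector for one OTU table to CLR values
#' `Z_p = log(X_p / g(X))`, where `X_p` is the observed count plus a
#' pseudocount of `1/depth` (added to every taxon, so zeros stay finite and
#' the adjustment vanishes as sequencing depth grows) and `g(X)` is the
#' geometric mean over the table's `P` taxa. The geometric mean is computed
#' in log space, so the transform is stable for large depths. CLR values of
#' any positive vector sum to zero.
#'
#' @param counts Raw counts for all `P` taxa of one table in one library.
#' @param depth Total reads of that library in that table (`sum(counts)` in
#'   normal use; must be positive).
#' @return Numeric vector of CLR values summing to 0.
#' @examples
#' clr_transform(c(10, 90), 100)
#' sum(clr_transform(c(0, 3, 7), 10))  # 0
#' @export
clr_transform <- function(counts, depth) {
  if (length(counts) < 1L) stop("counts must have length >= 1")
  if (!is.numeric(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0)
    stop("depth must be a single positive number")
  lx <- log(counts + 1 / depth)
  lx - mean(lx)
}
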