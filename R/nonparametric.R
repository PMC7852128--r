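#' Rank-based group tests on taxa abundance
#'
#' The nonparametric fallback for taxa whose regression fits fail: for each
#' taxon, a Wilcoxon rank-sum test (two group levels; exact enumeration when
#' both groups have at most 8 observations and there are no ties, otherwise
#' the tie-corrected normal approximation) or a Kruskal-Wallis test (more
#' than two levels, tie-corrected), on the taxon's relative abundance (or
#' CLR values). P-values are FDR-adjusted across the tested taxa.
#'
#' @param micro_set A `micro_set`.
#' @param table Table name.
#' @param group Clinical column with >= 2 observed levels.
#' @param on `"ra"` (default, the abundance scale) or `"clr"`.
#' @param method `"auto"` (default: Wilcoxon for two levels, Kruskal-Wallis
#'   otherwise) or `"kruskal"` to force the Kruskal-Wallis statistic even
#'   for two groups.
#' @param failed_only Optional `taxa_models` object; restricts testing to
#'   its non-converged taxa.
#' @return A tibble of `Taxa`, `statistic` (rank-sum W or Kruskal-Wallis H),
#'   `p`, `fdr_p`.
#' @export
rank_taxa_test <- function(micro_set, table, group, on = c("ra", "clr"),
                           failed_only = NULL, method = c("auto", "kruskal")) {
  on <- match.arg(on)
  method <- match.arg(method)
  sub <- ms_table(micro_set, table)
  if (!group %in% names(sub)) stop("group column '", group, "' not found")
  if (!is.null(failed_only)) {
    sub <- sub[sub$Taxa %in% failed_taxa(failed_only), , drop = FALSE]
    if (nrow(sub) == 0L) stop("no failed taxa to test")
  }
  g_all <- factor(sub[[group]])
  lv <- levels(droplevels(g_all))
  if (length(lv) < 2L) stop("group must have >= 2 levels")
  tab_g <- table(droplevels(g_all)) / length(unique(sub$Taxa))
  if (any(tab_g == 0)) stop("group level with 0 observations")
  rows <- lapply(split(sub, sub$Taxa), function(d) {
    v <- d[[on]]
    g <- droplevels(factor(d[[group]]))
    if (nlevels(g) == 2L && method == "auto") {
      ht <- suppressWarnings(wilcox.test(v ~ g))
    } else {
      ht <- kruskal.test(v ~ g)
    }
    tibble::tibble(Taxa = d$Taxa[1L], statistic = unname(ht$statistic),
                   p = ht$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[match(unique(sub$Taxa), out$Taxa), , drop = FALSE]
  out$fdr_p <- bh_adjust(out$p)
  out
}

#' Chi-squared tests on taxa presence
#'
#' For each taxon, a Pearson chi-square test (no continuity correction) of
#' the presence/absence indicator against the group. Degenerate taxa — all
#' present or all absent — get an NA statistic with `flag =
#' "degenerate"`; tables with any expected cell count below 5 are flagged
#' `"low-expected"` but still tested.
#'
#' @inheritParams rank_taxa_test
#' @return A tibble of `Taxa`, `statistic`, `df`, `p`, `fdr_p`, `flag`.
#' @export
presence_chisq <- function(micro_set, table, group, failed_only = NULL) {
  sub <- ms_table(micro_set, table)
  if (!group %in% names(sub)) stop("group column '", group, "' not found")
  if (!is.null(failed_only)) {
    sub <- sub[sub$Taxa %in% failed_taxa(failed_only), , drop = FALSE]
    if (nrow(sub) == 0L) stop("no failed taxa to test")
  }
  if (nlevels(droplevels(factor(sub[[group]]))) < 2L)
    stop("group must have >= 2 levels")
  rows <- lapply(split(sub, sub$Taxa), function(d) {
    g <- droplevels(factor(d[[group]]))
    b <- factor(d$bin, levels = c(0L, 1L))
    ct <- table(b, g)
    if (any(rowSums(ct) == 0))
      return(tibble::tibble(Taxa = d$Taxa[1L], statistic = NA_real_,
                            df = NA_real_, p = NA_real_, flag = "degenerate"))
    ht <- suppressWarnings(chisq.test(ct, correct = FALSE))
    tibble::tibble(Taxa = d$Taxa[1L], statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p = ht$p.value,
                   flag = if (any(ht$expected < 5)) "low-expected" else "ok")
  })
  out <- dplyr::bind_rows(rows)
  out <- out[match(unique(sub$Taxa), out$Taxa), , drop = FALSE]
  out$fdr_p <- NA_real_
  tested <- !is.na(out$p)
  out$fdr_p[tested] <- bh_adjust(out$p[tested])
  out[, c("Taxa", "statistic", "df", "p", "fdr_p", "flag")]
}
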