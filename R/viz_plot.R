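# Thin ggplot2 renderers over the *_data functions. Analyses and tests run
# on the data layer; these only draw.

#' Render a stacked bar chart of (estimated) taxa abundance
#' @param bars Output of [taxa_bars_data()] or [nb_bars_data()].
#' @return A ggplot object.
#' @export
plot_taxa_bars <- function(bars) {
  ggplot2::ggplot(bars, ggplot2::aes(x = .data$group, y = .data$abundance,
                                     fill = .data$Taxa)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "Relative abundance (%)", fill = "Taxa") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Render a Rocky Mountain plot
#' @param rmd Output of [rocky_mtn_cor_data()] or [rocky_mtn_model_data()].
#' @return A ggplot object.
#' @export
plot_rocky_mtn <- function(rmd) {
  rmd$ord <- seq_len(nrow(rmd))
  ylab <- if (identical(attr(rmd, "mode"), "model"))
    "signed -log(FDR p)" else "rank correlation"
  ggplot2::ggplot(rmd, ggplot2::aes(x = .data$ord, y = .data$y,
                                    fill = .data$phylum)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(data = rmd[rmd$labeled, , drop = FALSE],
                       ggplot2::aes(label = .data$label),
                       size = 2.5, vjust = -0.4) +
    ggplot2::labs(x = "Taxa", y = ylab, fill = "Phylum") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Render a correlation heatmap
#' @param mat Output of [cor_heatmap_data()].
#' @return A ggplot object.
#' @export
plot_cor_heatmap <- function(mat) {
  df <- tibble::tibble(
    Taxa = rep(taxon_label(rownames(mat)), times = ncol(mat)),
    covariate = rep(colnames(mat), each = nrow(mat)),
    r = as.vector(mat))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$covariate, y = .data$Taxa,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme_bw()
}

#' Render a forest plot of rate/odds ratios
#' @param fd Output of [forest_data()].
#' @return A ggplot object.
#' @export
plot_forest <- function(fd) {
  fd$Taxa <- factor(fd$Taxa, levels = fd$Taxa)
  ggplot2::ggplot(fd, ggplot2::aes(x = .data$ratio, y = .data$Taxa)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Ratio (log scale)", y = NULL) +
    ggplot2::theme_bw()
}

#' Render an ordination score plot with optional normal ellipses
#' @param ord An `ordination` object.
#' @param groups Optional group label per score row (for color and
#'   ellipses).
#' @param ellipse_level Confidence level for [ordination_ellipse()] paths;
#'   `NULL` for none.
#' @return A ggplot object.
#' @export
plot_ordination <- function(ord, groups = NULL, ellipse_level = 0.95) {
  sc <- ord$scores
  df <- tibble::tibble(x = sc[, 1],
                       y = if (ncol(sc) >= 2) sc[, 2] else 0)
  pct <- function(i) sprintf("%s (%.1f%%)", colnames(sc)[i],
                             100 * ord$explained[i])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(groups)) {
    df$group <- as.character(groups)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          color = .data$group))
    if (!is.null(ellipse_level) && ncol(sc) >= 2) {
      ell <- ordination_ellipse(sc, df$group, level = ellipse_level)
      if (nrow(ell))
        p <- p + ggplot2::geom_path(
          data = ell, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$group), inherit.aes = FALSE)
    }
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = pct(1),
                  y = if (ncol(sc) >= 2) pct(2) else NULL) +
    ggplot2::theme_bw()
}
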