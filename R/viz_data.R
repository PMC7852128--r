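# Taxon labels are rank paths like "Bacteria/Firmicutes/Bacilli"; plots use
# the phylum (2nd element by default) for color and the final rank for text.
taxon_phylum <- function(taxa, sep = "/", index = 2L) {
  vapply(strsplit(taxa, sep, fixed = TRUE), function(p)
    if (length(p) >= index) p[[index]] else p[[length(p)]], character(1))
}

taxon_label <- function(taxa, sep = "/") {
  vapply(strsplit(taxa, sep, fixed = TRUE), function(p) p[[length(p)]],
         character(1))
}

# Shared top-k rule for stacked bars: keep the `top_taxa` largest grand
# means, exempt anything above `ra_cutoff`, merge the rest into "Other".
bars_aggregate <- function(df, top_taxa = NULL, ra_cutoff = NULL) {
  grand <- df |>
    dplyr::group_by(.data$Taxa) |>
    dplyr::summarise(grand = mean(.data$abundance), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$grand))
  keep <- grand$Taxa
  if (!is.null(top_taxa)) {
    keep <- utils::head(grand$Taxa[grand$Taxa != "Other"], top_taxa)
    if (!is.null(ra_cutoff))
      keep <- union(keep, grand$Taxa[grand$grand >= ra_cutoff])
  }
  df$Taxa[!df$Taxa %in% keep] <- "Other"
  out <- df |>
    dplyr::group_by(.data$group, .data$Taxa) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop")
  lev <- c(intersect(grand$Taxa, setdiff(unique(out$Taxa), "Other")),
           if ("Other" %in% out$Taxa) "Other")
  out$Taxa <- factor(out$Taxa, levels = lev)
  dplyr::arrange(out, .data$group, .data$Taxa)
}

#' Data behind stacked bar charts of average taxa abundance
#'
#' Mean relative abundance (percent) per taxon within each group level, or
#' overall when `group` is `NULL`. Within each bar the abundances sum to
#' 100. With `top_taxa`, all but the most abundant taxa (by grand mean RA)
#' merge into `"Other"`, except taxa whose grand mean exceeds `ra_cutoff`.
#'
#' @param micro_set A `micro_set`.
#' @param table Table name.
#' @param group Optional clinical grouping column.
#' @param top_taxa Optional number of taxa to show individually.
#' @param ra_cutoff Optional percent; taxa above it never merge into Other.
#' @return A tibble of `group`, `Taxa` (ordered by abundance, Other last),
#'   `abundance`.
#' @export
taxa_bars_data <- function(micro_set, table, group = NULL, top_taxa = NULL,
                           ra_cutoff = NULL) {
  sub <- ms_table(micro_set, table)
  if (!is.null(group) && !group %in% names(sub))
    stop("group column '", group, "' not found")
  if (!is.null(top_taxa) && top_taxa < 1) stop("top_taxa must be >= 1")
  sub$group <- if (is.null(group)) "all" else as.character(sub[[group]])
  means <- sub |>
    dplyr::group_by(.data$group, .data$Taxa) |>
    dplyr::summarise(abundance = mean(.data$ra), .groups = "drop")
  bars_aggregate(means, top_taxa, ra_cutoff)
}

#' Data behind parametric stacked bar charts
#'
#' Back-transforms fitted per-taxon coefficients to estimated composition:
#' at each requested covariate profile the estimated mean count is
#' `mu = exp(x' beta + o)` (negative binomial; `o` is the mean log depth
#' when the model has an offset) or `mu = plogis(x' beta)` scaled by depth
#' (beta-binomial), and the estimated relative abundance of each taxon is
#' `100 mu / sum(mu)` over the converged taxa. Covariates named in
#' `covariates` are varied — categorical over their levels, continuous over
#' a grid (default 20 points across the observed range) — while all other
#' covariates sit at their reference level (categorical) or mean
#' (continuous).
#'
#' @param models A `taxa_models` object.
#' @param covariates One or two model covariate names (one categorical, one
#'   continuous, or a categorical x continuous pair).
#' @param top_taxa Taxa to show individually (default 5, the rest in
#'   `"Other"`).
#' @param ra_cutoff Optional percent; taxa above it never merge.
#' @param grid_n Grid points for a continuous covariate (default 20).
#' @param grid Optional explicit grid values for the continuous covariate.
#' @return A tibble of `group` (covariate profile label), `Taxa`,
#'   `abundance`, plus one column per varied covariate.
#' @export
nb_bars_data <- function(models, covariates, top_taxa = 5, ra_cutoff = NULL,
                         grid_n = 20, grid = NULL) {
  stopifnot(inherits(models, "taxa_models"))
  vars <- all.vars(models$formula)
  if (!all(covariates %in% vars))
    stop("covariate(s) not in the model: ",
         paste(setdiff(covariates, vars), collapse = ", "))
  if (length(covariates) > 2L) stop("at most two covariates")
  lib <- models$lib_data
  # profile grid for the varied covariates
  values <- lapply(covariates, function(v) {
    x <- lib[[v]]
    if (is.numeric(x)) {
      grid %||% seq(min(x), max(x), length.out = grid_n)
    } else factor(levels(factor(x)), levels = levels(factor(x)))
  })
  names(values) <- covariates
  prof <- if (length(values)) expand.grid(values, stringsAsFactors = FALSE)
    else data.frame(row.names = "1")
  # everything else held at reference / mean
  for (v in setdiff(vars, covariates)) {
    x <- lib[[v]]
    prof[[v]] <- if (is.numeric(x)) mean(x) else
      factor(levels(factor(x))[1L], levels = levels(factor(x)))
  }
  Xp <- model.matrix(delete.response(models$terms), prof,
                     xlev = models$xlevels)
  o_bar <- if (models$offset) mean(models$log_offset) else 0
  mu <- vapply(models$fits, function(fit) {
    eta <- drop(Xp %*% fit$coefficients)
    if (models$family == "negbin") exp(eta + o_bar) else plogis(eta)
  }, numeric(nrow(Xp)))
  mu <- matrix(mu, nrow = nrow(Xp))
  ra <- 100 * mu / rowSums(mu)
  lab <- if (length(covariates))
    apply(prof[covariates], 1L, function(r)
      paste(format(r, trim = TRUE), collapse = ", "))
  else rep("all", nrow(Xp))
  df <- tibble::tibble(
    group = rep(lab, times = length(models$fits)),
    Taxa = rep(names(models$fits), each = nrow(Xp)),
    abundance = as.vector(ra))
  out <- bars_aggregate(df, top_taxa, ra_cutoff)
  if (!length(covariates)) return(out)
  info <- tibble::as_tibble(prof[covariates])
  info$group <- lab
  dplyr::left_join(out, info, by = "group")
}

#' Data behind correlation Rocky Mountain plots
#'
#' Rank correlation between each taxon's CLR values and a numeric covariate
#' across libraries; a Manhattan-plot variant where the signed correlation
#' is the peak height, taxa are colored by phylum, and correlations whose
#' magnitude reaches `label_cutoff` are marked for labeling.
#'
#' @param micro_set A `micro_set`.
#' @param table Table name.
#' @param covariate Numeric, non-constant clinical column.
#' @param method `"spearman"` (default) or `"kendall"`.
#' @param label_cutoff Magnitude at which a taxon is labeled (default 0.3).
#' @return A tibble of `Taxa`, `label`, `phylum`, `y`, `labeled`; `mode`
#'   attribute `"correlation"`.
#' @export
rocky_mtn_cor_data <- function(micro_set, table, covariate,
                               method = c("spearman", "kendall"),
                               label_cutoff = 0.3) {
  method <- match.arg(method)
  sub <- ms_table(micro_set, table)
  if (!covariate %in% names(sub)) stop("covariate '", covariate, "' not found")
  x <- sub[[covariate]][match(unique(sub$Lib), sub$Lib)]
  if (!is.numeric(x)) stop("covariate must be numeric")
  if (isTRUE(sd(x) == 0)) stop("covariate is constant")
  m <- ms_matrix(micro_set, table, "clr")
  xs <- sub[[covariate]][match(rownames(m), sub$Lib)]
  y <- apply(m, 2L, function(v) suppressWarnings(cor(v, xs, method = method)))
  out <- tibble::tibble(
    Taxa = colnames(m), label = taxon_label(colnames(m)),
    phylum = taxon_phylum(colnames(m)),
    y = unname(y), labeled = !is.na(y) & abs(y) >= label_cutoff)
  attr(out, "mode") <- "correlation"
  out
}

#' Data behind model-based Rocky Mountain plots
#'
#' For one model coefficient, each taxon's peak is the log-transformed FDR
#' p-value with the sign of the estimated effect:
#' `y = sign(beta) * |log(fdr_p)|`, so taxa more abundant in the exposed
#' group point up and less abundant taxa point down. A zero FDR p-value is
#' capped at the smallest positive double with a logged note.
#'
#' @param estimates An estimate table from [estimate_table()].
#' @param coefficient Coefficient label to plot.
#' @param log_base `"e"` (default) or `"10"`.
#' @param label_cutoff Magnitude of `y` at which a taxon is labeled
#'   (default: FDR p of 0.05 on the chosen log scale).
#' @return A tibble of `Taxa`, `label`, `phylum`, `ratio`, `y`, `labeled`;
#'   `mode` attribute `"model"`.
#' @export
rocky_mtn_model_data <- function(estimates, coefficient, log_base = c("e", "10"),
                                 label_cutoff = NULL) {
  log_base <- match.arg(log_base)
  lg <- if (log_base == "e") log else log10
  sub <- estimates[estimates$Coefficient == coefficient, , drop = FALSE]
  if (nrow(sub) == 0L) stop("coefficient '", coefficient, "' not in estimates")
  label_cutoff <- label_cutoff %||% abs(lg(0.05))
  p <- sub$fdr_p
  if (any(p == 0)) {
    mt_log("rocky_mtn_model_data: fdr_p of 0 capped at .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  beta_sign <- sign(log(sub$ratio))
  y <- ifelse(beta_sign == 0, 0, -beta_sign * lg(p))
  out <- tibble::tibble(
    Taxa = sub$Taxa, label = taxon_label(sub$Taxa),
    phylum = taxon_phylum(sub$Taxa), ratio = sub$ratio,
    y = y, labeled = abs(y) >= label_cutoff)
  attr(out, "mode") <- "model"
  out
}

#' Taxa x covariate matrix of rank correlations (heatmap data)
#'
#' Entry (taxon, covariate) is the rank correlation between the taxon's CLR
#' values and the covariate across libraries. Constant covariates are
#' dropped with a warning.
#'
#' @param micro_set A `micro_set`.
#' @param table Table name.
#' @param covariates Numeric clinical column names.
#' @param method `"spearman"` (default) or `"kendall"`.
#' @return Numeric matrix, taxa in rows, covariates in columns.
#' @export
cor_heatmap_data <- function(micro_set, table, covariates,
                             method = c("spearman", "kendall")) {
  method <- match.arg(method)
  m <- ms_matrix(micro_set, table, "clr")
  lib_data <- ms_lib_data(micro_set, table)
  cols <- list()
  for (v in covariates) {
    if (!v %in% names(lib_data)) stop("covariate '", v, "' not found")
    x <- lib_data[[v]][match(rownames(m), lib_data$Lib)]
    if (!is.numeric(x)) stop("covariate '", v, "' must be numeric")
    if (isTRUE(sd(x) == 0)) {
      warning("constant covariate '", v, "' dropped")
      next
    }
    cols[[v]] <- apply(m, 2L, function(cl)
      suppressWarnings(cor(cl, x, method = method)))
  }
  if (!length(cols)) stop("no usable covariates")
  do.call(cbind, cols)
}

#' Forest-plot data for one model coefficient
#'
#' Estimate rows for one coefficient, sorted by ratio, optionally keeping
#' the `top` taxa with the largest absolute log ratio.
#'
#' @param estimates An estimate table from [estimate_table()].
#' @param coefficient Coefficient label.
#' @param top Optional number of taxa to keep.
#' @return A tibble of `Taxa`, `ratio`, `ci_low`, `ci_high`, `fdr_p`.
#' @export
forest_data <- function(estimates, coefficient, top = NULL) {
  sub <- estimates[estimates$Coefficient == coefficient, , drop = FALSE]
  if (nrow(sub) == 0L) stop("coefficient '", coefficient, "' not in estimates")
  if (!is.null(top))
    sub <- sub[order(abs(log(sub$ratio)), decreasing = TRUE), ][
      seq_len(min(top, nrow(sub))), ]
  sub <- sub[order(sub$ratio), , drop = FALSE]
  dplyr::select(sub, "Taxa", "ratio", "ci_low", "ci_high", "fdr_p")
}
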