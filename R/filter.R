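#' Aggregate rare taxa into an "Other" category
#'
#' A taxon is aggregated when any of three rules fires, all evaluated on the
#' unfiltered table: (a) it is present (`bin == 1`) in fewer than
#' `prev_cutoff` percent of the table's libraries; (b) its relative
#' abundance is below `ra_cutoff` percent in every library; (c) it is named
#' in `aggregate_taxa`. The union of the three rules is summed per library
#' into a single `"Other"` taxon (merged into an existing `"Other"` row if
#' one is already present), so per-library depth is conserved. Relative
#' abundance, CLR and presence are recomputed on the filtered table, whose
#' taxon count has changed. A report of kept and aggregated taxa is logged.
#'
#' @param micro_set A `micro_set`.
#' @param table Table to filter; `NULL` (default) filters every table.
#' @param prev_cutoff Prevalence cutoff, percent of libraries in \[0, 100\].
#' @param ra_cutoff Relative-abundance cutoff, percent in \[0, 100\]. A
#'   taxon reaching `ra_cutoff` in at least one library is kept by rule (b).
#' @param aggregate_taxa Taxon labels to force into `"Other"`.
#' @return The filtered `micro_set`.
#' @examples
#' \donttest{
#' sim <- simulate_micro(n_lib = 20, n_taxa = 8, seed = 1)
#' ms <- build_micro_set(sim$otu_tabs, sim$clinical, lib_col = "Lib")
#' otu_filter(ms, prev_cutoff = 5, ra_cutoff = 0.1)
#' }
#' @export
otu_filter <- function(micro_set, table = NULL, prev_cutoff = 0, ra_cutoff = 0,
                       aggregate_taxa = character()) {
  stopifnot(inherits(micro_set, "micro_set"))
  if (prev_cutoff < 0 || prev_cutoff > 100) stop("prev_cutoff must be in [0, 100]")
  if (ra_cutoff < 0 || ra_cutoff > 100) stop("ra_cutoff must be in [0, 100]")
  targets <- if (is.null(table)) ms_tables(micro_set) else as.character(table)
  if (!all(targets %in% ms_tables(micro_set)))
    stop("unknown table: ", setdiff(targets, ms_tables(micro_set))[1L])
  all_taxa <- unique(micro_set$Taxa[micro_set$Table %in% targets])
  bad <- setdiff(aggregate_taxa, all_taxa)
  if (length(bad))
    stop("aggregate_taxa not found in table(s): ", paste(bad, collapse = ", "))

  blocks <- lapply(ms_tables(micro_set), function(tb) {
    sub <- micro_set[micro_set$Table == tb, , drop = FALSE]
    if (!tb %in% targets) return(sub)
    stats <- sub |>
      dplyr::group_by(.data$Taxa) |>
      dplyr::summarise(prev = 100 * mean(.data$bin), max_ra = max(.data$ra),
                       .groups = "drop")
    drop <- stats$Taxa[stats$prev < prev_cutoff | stats$max_ra < ra_cutoff]
    drop <- union(drop, intersect(aggregate_taxa, stats$Taxa))
    drop <- setdiff(drop, "Other")
    keep <- setdiff(stats$Taxa, drop)
    if (length(keep) == 0L)
      stop("all taxa of table '", tb, "' would be aggregated")
    mt_log("otu_filter [", tb, "]: kept ", length(keep), " taxa, aggregated ",
           length(drop), " into 'Other'",
           if (length(drop)) paste0(": ", paste(drop, collapse = ", ")) else "")
    if (length(drop) == 0L) return(sub)
    kept_rows <- sub[!sub$Taxa %in% drop & sub$Taxa != "Other", , drop = FALSE]
    other <- sub[sub$Taxa %in% c(drop, "Other"), , drop = FALSE] |>
      dplyr::group_by(.data$Lib) |>
      dplyr::summarise(cts = sum(.data$cts), .groups = "drop")
    libs <- unique(sub$Lib)
    other_rows <- sub[sub$Taxa == sub$Taxa[1L], , drop = FALSE]  # template block
    other_rows <- other_rows[match(libs, other_rows$Lib), , drop = FALSE]
    other_rows$Taxa <- "Other"
    other_rows$cts <- other$cts[match(libs, other$Lib)]
    dplyr::bind_rows(kept_rows, other_rows)
  })
  long <- dplyr::bind_rows(blocks)
  long <- ms_derive(long[, c("Table", "Taxa", "Lib", "cts",
                             ms_clinical_vars(micro_set))])
  long <- long[, c("Table", "Taxa", "Lib", "cts", "Total", "ra", "clr", "bin",
                   ms_clinical_vars(micro_set))]
  new_micro_set(long, tab_names = ms_tables(micro_set),
                clin_vars = ms_clinical_vars(micro_set))
}
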