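#' Merge OTU tables and clinical data into a tidy micro_set
#'
#' Builds the pipeline's central object: a long tibble with one row per
#' (OTU table, taxon, sequencing library), carrying the raw count (`cts`),
#' the library's total reads in that table (`Total`), relative abundance in
#' percent (`ra`), the centered log-ratio value (`clr`), a presence
#' indicator (`bin`), and every clinical covariate repeated down each taxon
#' block. Table blocks keep the order of `otu_tabs`; taxa and libraries keep
#' their input order.
#'
#' @param otu_tabs A named list of [otu_tbl] objects (names override each
#'   table's own `name`), or a single `otu_tbl`.
#' @param clinical A data frame of per-library covariates (e.g. from
#'   [read_clinical()]).
#' @param lib_col Name of the clinical column holding library IDs. Defaults
#'   to the `id_col` attribute set by [read_clinical()].
#' @param complete_clin When `TRUE`, keep only libraries present in both the
#'   OTU tables and the clinical table (symmetric inner join); every dropped
#'   ID is logged. When `FALSE`, libraries missing clinical data are kept
#'   with `NA` covariates.
#' @return A `micro_set` tibble.
#' @seealso [otu_filter()], [alpha_div()], [nb_mods()]
#' @export
build_micro_set <- function(otu_tabs, clinical, lib_col = attr(clinical, "id_col"),
                            complete_clin = TRUE) {
  if (inherits(otu_tabs, "otu_tbl")) otu_tabs <- list(otu_tabs)
  stopifnot(is.list(otu_tabs), length(otu_tabs) >= 1L)
  if (is.null(names(otu_tabs)) || any(!nzchar(names(otu_tabs))))
    names(otu_tabs) <- vapply(otu_tabs, function(t) t$name, character(1))
  if (anyDuplicated(names(otu_tabs))) stop("duplicate OTU table names")
  if (is.null(lib_col)) stop("lib_col must name the clinical library-ID column")
  if (!lib_col %in% names(clinical)) stop("column '", lib_col, "' not in clinical data")
  clinical <- tibble::as_tibble(clinical)
  clin_ids <- as.character(clinical[[lib_col]])
  if (anyDuplicated(clin_ids))
    stop("duplicate library IDs in clinical data: ",
         paste(unique(clin_ids[duplicated(clin_ids)]), collapse = ", "))

  seq_ids <- unique(unlist(lapply(otu_tabs, function(t) t$libraries)))
  if (!any(seq_ids %in% clin_ids))
    stop("no overlap between OTU table libraries and clinical library IDs")
  keep_ids <- seq_ids
  if (complete_clin) {
    drop_seq <- setdiff(seq_ids, clin_ids)
    drop_clin <- setdiff(clin_ids, seq_ids)
    if (length(drop_seq))
      mt_log("complete_clin: dropping ", length(drop_seq),
             " librar", if (length(drop_seq) == 1) "y" else "ies",
             " with no clinical data: ", paste(drop_seq, collapse = ", "))
    if (length(drop_clin))
      mt_log("complete_clin: dropping ", length(drop_clin),
             " clinical record(s) with no sequence data: ",
             paste(drop_clin, collapse = ", "))
    keep_ids <- intersect(seq_ids, clin_ids)
    if (length(keep_ids) == 0L) stop("no overlapping libraries after join")
  }

  blocks <- purrr::imap(otu_tabs, function(tab, nm) {
    libs <- intersect(tab$libraries, keep_ids)
    if (length(libs) == 0L) stop("table '", nm, "' has no retained libraries")
    cts <- tab$counts[, libs, drop = FALSE]
    depth <- colSums(cts)
    if (any(depth == 0))
      stop("library with zero reads in table '", nm, "': ",
           paste(libs[depth == 0], collapse = ", "))
    tibble::tibble(
      Table = nm,
      Taxa = rep(tab$taxa, each = length(libs)),
      Lib = rep(libs, times = length(tab$taxa)),
      cts = as.integer(t(cts)))
  })
  long <- dplyr::bind_rows(blocks)
  long <- ms_derive(long)

  clin2 <- clinical
  names(clin2)[names(clin2) == lib_col] <- "Lib"
  clin2$Lib <- as.character(clin2$Lib)
  out <- dplyr::left_join(long, clin2, by = "Lib")
  new_micro_set(out, tab_names = names(otu_tabs),
                clin_vars = setdiff(names(clin2), "Lib"))
}

new_micro_set <- function(df, tab_names, clin_vars) {
  structure(tibble::as_tibble(df),
            tab_names = tab_names, clin_vars = clin_vars,
            class = c("micro_set", class(tibble::tibble())))
}

# Recompute Total/ra/clr/bin from cts within each (Table, Lib) block.
# Central contract: every operation that alters counts calls this.
ms_derive <- function(long) {
  long |>
    dplyr::group_by(.data$Table, .data$Lib) |>
    dplyr::mutate(
      Total = sum(.data$cts),
      ra = 100 * .data$cts / .data$Total,
      clr = clr_transform(.data$cts, .data$Total[1L]),
      bin = as.integer(.data$cts > 0)) |>
    dplyr::ungroup()
}

#' @export
print.micro_set <- function(x, ...) {
  tabs <- attr(x, "tab_names")
  cat("# micro_set: ", length(tabs), " OTU table(s) [",
      paste(tabs, collapse = ", "), "], ",
      length(unique(x$Lib)), " libraries, ", nrow(x), " rows\n", sep = "")
  NextMethod()
}

#' List the OTU tables of a micro_set
#' @param micro_set A `micro_set`.
#' @return Character vector of table names, in block order.
#' @export
ms_tables <- function(micro_set) attr(micro_set, "tab_names")

#' Clinical covariate names carried by a micro_set
#' @param micro_set A `micro_set`.
#' @return Character vector of covariate column names.
#' @export
ms_clinical_vars <- function(micro_set) attr(micro_set, "clin_vars")

# libraries x taxa matrix of `value` for one table; rows ordered by the
# table's library order, columns by its taxa order.
ms_matrix <- function(micro_set, table, value = "cts") {
  sub <- ms_table(micro_set, table)
  taxa <- unique(sub$Taxa)
  libs <- unique(sub$Lib)
  m <- matrix(NA_real_, nrow = length(libs), ncol = length(taxa),
              dimnames = list(libs, taxa))
  m[cbind(match(sub$Lib, libs), match(sub$Taxa, taxa))] <- sub[[value]]
  m
}

ms_table <- function(micro_set, table) {
  table <- as.character(table)
  if (!table %in% ms_tables(micro_set))
    stop("table '", table, "' not in micro_set (tables: ",
         paste(ms_tables(micro_set), collapse = ", "), ")")
  micro_set[micro_set$Table == table, , drop = FALSE]
}

#' One row per library with its clinical covariates
#' @param micro_set A `micro_set`.
#' @param table Optional table to restrict to (libraries can differ between
#'   tables).
#' @return A tibble of `Lib` plus the clinical covariates.
#' @export
ms_lib_data <- function(micro_set, table = NULL) {
  sub <- if (is.null(table)) micro_set else ms_table(micro_set, table)
  # any column the user added to the tibble counts as library-level data
  keep <- setdiff(names(sub), c("Table", "Taxa", "cts", "Total", "ra",
                                "clr", "bin"))
  sub |>
    dplyr::distinct(.data$Lib, .keep_all = TRUE) |>
    dplyr::select(dplyr::all_of(union("Lib", keep)))
}

#' Write a micro_set as a flat CSV
#'
#' @param micro_set A `micro_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_micro_set <- function(micro_set, path) {
  write.csv(as.data.frame(micro_set), path, row.names = FALSE)
  invisible(path)
}

#' Read a micro_set written by [write_micro_set()]
#'
#' Derived columns are recomputed from the stored counts rather than trusted
#' from the file, so a round trip always satisfies the micro_set contract.
#'
#' @param path CSV produced by [write_micro_set()].
#' @return A `micro_set` tibble.
#' @export
read_micro_set <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- c("Table", "Taxa", "Lib", "cts")
  if (!all(need %in% names(df)))
    stop("'", path, "' is not a micro_set CSV (needs columns ",
         paste(need, collapse = ", "), ")")
  df$Lib <- as.character(df$Lib)
  clin <- setdiff(names(df), c(need, "Total", "ra", "clr", "bin"))
  for (nm in clin) if (is.character(df[[nm]]))
    df[[nm]] <- factor(df[[nm]], levels = unique(df[[nm]]))
  long <- ms_derive(tibble::as_tibble(df[c(need, clin)]))
  long <- long[, c(need[1:3], "cts", "Total", "ra", "clr", "bin", clin)]
  new_micro_set(long, tab_names = unique(df$Table), clin_vars = clin)
}
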