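#' Read a QIIME-classic OTU count table
#'
#' Parses the "classic" tab- or comma-delimited OTU table layout: the first
#' column holds taxon labels (rank paths such as
#' `"Bacteria/Firmicutes/Bacilli"`), the remaining columns hold read counts
#' for each sequencing library, and the header row holds the library IDs.
#' Comment lines beginning `#` are skipped, except a header line beginning
#' `#OTU ID`, which is treated as the header with the leading `#` stripped.
#'
#' @param path Path to the table.
#' @param name Label for the taxonomic rank of this table (e.g. `"Genus"`).
#' @param delimiter Field delimiter; when `NULL` (default), tab is tried
#'   first and comma is used if the header contains no tab.
#' @return An `otu_tbl` object: a list with `name`, `taxa`, `libraries`, and
#'   an integer `counts` matrix (taxa x libraries).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("#OTU ID\tL1\tL2", "Bacteria/Firmicutes\t1\t2",
#'              "Bacteria/Proteobacteria\t3\t4"), tf)
#' tab <- read_otu_table(tf, name = "Phylum")
#' tab$counts
#' @export
read_otu_table <- function(path, name, delimiter = NULL) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("OTU table file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  # drop comment lines, but keep a '#OTU ID' header (classic QIIME dialect)
  is_comment <- startsWith(lines, "#") & !startsWith(lines, "#OTU ID")
  lines <- lines[!is_comment]
  if (length(lines) < 2L) stop("OTU table '", path, "' is empty (no taxa rows)")
  if (is.null(delimiter)) delimiter <- if (grepl("\t", lines[[1L]])) "\t" else ","
  split_row <- function(l) strsplit(l, delimiter, fixed = TRUE)[[1L]]
  header <- split_row(lines[[1L]])
  header[1L] <- sub("^#", "", header[1L])
  libs <- trimws(header[-1L])
  if (length(libs) == 0L) stop("OTU table '", path, "' has no library columns")
  if (anyDuplicated(libs))
    stop("duplicate library IDs in '", path, "': ",
         paste(unique(libs[duplicated(libs)]), collapse = ", "))
  body <- lapply(lines[-1L], split_row)
  n_field <- lengths(body)
  if (any(n_field != length(header)))
    stop("row ", which(n_field != length(header))[1L] + 1L, " of '", path,
         "' has ", n_field[n_field != length(header)][1L],
         " fields; expected ", length(header))
  taxa <- trimws(vapply(body, `[[`, character(1), 1L))
  if (anyDuplicated(taxa))
    stop("duplicate taxon labels in '", path, "': ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  counts <- matrix(NA_real_, nrow = length(taxa), ncol = length(libs),
                   dimnames = list(taxa, libs))
  for (i in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1L]
      stop("non-numeric count '", body[[i]][-1L][j], "' at taxon '", taxa[i],
           "', library '", libs[j], "' in '", path, "'")
    }
    counts[i, ] <- vals
  }
  if (any(counts < 0)) stop("negative counts in '", path, "'")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("non-integer counts in '", path, "'")
  storage.mode(counts) <- "integer"
  otu_tbl(name = name, counts = counts)
}

#' Construct an OTU table object from a count matrix
#'
#' @param name Rank label for the table.
#' @param counts Non-negative integer matrix, taxa in rows (rownames) and
#'   libraries in columns (colnames).
#' @return An `otu_tbl` object.
#' @export
otu_tbl <- function(name, counts) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("OTU table '", name, "' must have at least 1 taxon and 1 library")
  if (any(counts < 0)) stop("OTU table '", name, "' has negative counts")
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon labels")
  if (anyDuplicated(colnames(counts))) stop("duplicate library IDs")
  structure(
    list(name = as.character(name), taxa = rownames(counts),
         libraries = colnames(counts), counts = counts),
    class = "otu_tbl")
}

#' @export
print.otu_tbl <- function(x, ...) {
  cat("<otu_tbl> ", x$name, ": ", length(x$taxa), " taxa x ",
      length(x$libraries), " libraries\n", sep = "")
  invisible(x)
}

#' Write an OTU table in the classic tab-delimited layout
#'
#' @param x An `otu_tbl`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_tbl"))
  header <- paste(c("#OTU ID", x$libraries), collapse = "\t")
  rows <- vapply(seq_along(x$taxa), function(i)
    paste(c(x$taxa[i], x$counts[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a clinical metadata table
#'
#' One row per sequencing library. Columns where every non-missing entry
#' parses as a number become numeric; all other columns become factors with
#' levels in first-seen order, so the first observed level is the modeling
#' reference.
#'
#' @param path CSV or TSV file (delimiter auto-detected from the header).
#' @param id_column Name of the column holding library IDs.
#' @return A tibble with attribute `id_col` naming the library-ID column;
#'   the ID column itself is kept as character.
#' @export
read_clinical <- function(path, id_column) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("clinical file '", path, "' is empty")
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("clinical file '", path, "' has no rows")
  if (!id_column %in% names(df))
    stop("id column '", id_column, "' not found in '", path, "'; columns: ",
         paste(names(df), collapse = ", "))
  ids <- trimws(df[[id_column]])
  if (anyDuplicated(ids))
    stop("duplicate library IDs in clinical table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  df[[id_column]] <- ids
  for (nm in setdiff(names(df), id_column)) {
    v <- df[[nm]]
    num <- suppressWarnings(as.numeric(v))
    if (all(is.na(num) == (is.na(v) | v %in% c("", "NA")))) {
      df[[nm]] <- num
    } else {
      df[[nm]] <- factor(v, levels = unique(v[!is.na(v) & v != ""]))
    }
  }
  out <- tibble::as_tibble(df)
  attr(out, "id_col") <- id_column
  out
}
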