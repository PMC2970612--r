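#' Construct a dataset
#'
#' A dataset is the unit of Boolean algebra: a named table with one
#' designated identifier column (the "touch point") and arbitrary
#' attribute columns.  All cells are uninterpreted strings; attribute
#' cells may be empty, identifier cells may not.  Duplicate identifier
#' values across rows are permitted (an entity may carry several
#' annotation rows).  Cell values are whitespace-trimmed on
#' construction, which is what makes the write/read round trip exact.
#'
#' @param table a data.frame; all columns are coerced to character and
#'   trimmed.
#' @param name unique non-empty label used to refer to the dataset in
#'   queries.
#' @param id_column name of the identifier column; defaults to the
#'   first column.
#' @return an object of class `bm_dataset`.
#' @export
bm_dataset <- function(table, name, id_column = NULL) {
  if (!is.data.frame(table)) stop("`table` must be a data.frame")
  if (ncol(table) == 0L) stop("dataset must have at least one column")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("dataset `name` must be a non-empty string")
  cols <- colnames(table)
  if (is.null(id_column)) id_column <- cols[[1L]]
  if (!id_column %in% cols)
    stop(sprintf("id_column '%s' is not a column of the table (available: %s)",
                 id_column, paste(cols, collapse = ", ")))
  tab <- as.data.frame(lapply(table, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    trimws(x)
  }), stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE)
  if (nrow(table) == 0L) {
    tab <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                         check.names = FALSE)
  }
  colnames(tab) <- cols
  bad <- which(!nzchar(tab[[id_column]]))
  if (length(bad))
    stop(sprintf("empty identifier in column '%s' at row %d", id_column, bad[[1L]]))
  structure(list(name = name, id_column = id_column, table = tab),
            class = "bm_dataset")
}

#' @export
print.bm_dataset <- function(x, ...) {
  cat(sprintf("<bm_dataset> '%s': %d rows, %d columns (touch point: '%s')\n",
              x$name, nrow(x$table), ncol(x$table), x$id_column))
  cat("columns:", paste(colnames(x$table), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.bm_dataset <- function(x) dim(x$table)

#' Identifier values of a dataset, in row order
#' @param dataset a `bm_dataset`.
#' @return character vector, one entry per row.
#' @export
identifiers <- function(dataset) {
  stopifnot(inherits(dataset, "bm_dataset"))
  dataset$table[[dataset$id_column]]
}

# Shared delimited reader: header mandatory, everything character,
# RFC-style quoting (quoted fields may hold the delimiter; embedded
# quotes are doubled).
.read_delim <- function(path, delimiter = "\t") {
  utils::read.table(path, sep = delimiter, header = TRUE, quote = "\"",
                    colClasses = "character", na.strings = character(0),
                    comment.char = "", blank.lines.skip = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' Read a delimited table as a dataset
#'
#' The first line must be a header.  Cells are whitespace-trimmed; an
#' empty identifier cell is an error naming the offending file line.
#' TSV is the canonical dialect; CSV is accepted with RFC-style
#' quoting (quoted fields may contain the delimiter; embedded quotes
#' are doubled).
#'
#' @param path file path.
#' @param delimiter field separator, `"\t"` by default.
#' @param id_column identifier column name; default: first header column.
#' @param name dataset name; default: the file stem.
#' @return a `bm_dataset`.
#' @export
read_dataset <- function(path, delimiter = "\t", id_column = NULL, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- .read_delim(path, delimiter)
  cols <- colnames(tab)
  if (is.null(id_column)) id_column <- cols[[1L]]
  if (!id_column %in% cols)
    stop(sprintf("header of '%s' lacks id_column '%s' (available: %s)",
                 path, id_column, paste(cols, collapse = ", ")))
  ids <- trimws(as.character(tab[[id_column]]))
  bad <- which(is.na(ids) | !nzchar(ids))
  if (length(bad))
    stop(sprintf("empty identifier in column '%s' of '%s' at line %d",
                 id_column, path, bad[[1L]] + 1L))
  bm_dataset(tab, name = name, id_column = id_column)
}

#' Write a dataset to a delimited file
#'
#' Cells containing the delimiter, a quote or a newline are quoted so
#' that `read_dataset(write_dataset(d))` reproduces `d`'s columns, row
#' order and cell values exactly.
#'
#' @param dataset a `bm_dataset`.
#' @param path output file path.
#' @param delimiter field separator, `"\t"` by default.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, delimiter = "\t") {
  stopifnot(inherits(dataset, "bm_dataset"))
  data.table::fwrite(dataset$table, file = path, sep = delimiter,
                     quote = "auto", qmethod = "double", col.names = TRUE,
                     na = "", eol = "\n")
  invisible(path)
}

#' Extract (identifier, fingerprint) pairs from a FASTA file
#'
#' Each record yields one pair: the identifier is the header token
#' before the first whitespace, the fingerprint is the concatenated
#' sequence lines canonicalized as a sequence (whitespace stripped,
#' upper-cased).  No deduplication is performed: two records with the
#' same sequence yield two pairs with equal fingerprints.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `identifier` and `fingerprint`.
#' @export
read_fasta_fingerprints <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(identifier = character(0), fingerprint = character(0),
                      stringsAsFactors = FALSE))
  if (!startsWith(trimws(lines[[1L]]), ">"))
    stop(sprintf("malformed FASTA '%s': sequence data before first header", path))
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("package 'Biostrings' is required to read FASTA files")
  recs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(recs))
  if (any(!nzchar(ids))) stop(sprintf("FASTA '%s' contains an empty record ID", path))
  data.frame(identifier = ids,
             fingerprint = canonicalize_fingerprint("sequence", as.character(recs)),
             stringsAsFactors = FALSE, row.names = NULL)
}
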