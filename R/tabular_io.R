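# Delimited-table reading and writing. Field splitting and CSV quoting are
# delegated to base R (count.fields / read.table); this layer adds the
# contract: explicit header flag, duplicate-ID and ragged-row diagnostics,
# numeric-cell policy and column type inference.

# Split input into physical lines, tolerant of \n and \r\n.
split_input_lines <- function(file = NULL, text = NULL) {
  if (!is.null(text)) {
    raw <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  } else {
    if (!file.exists(file)) stop(sprintf("cannot read input file '%s'", file))
    raw <- readLines(file, warn = FALSE, encoding = "UTF-8")
  }
  raw <- sub("\r$", "", raw)
  # drop trailing blank lines only
  while (length(raw) > 0L && !nzchar(raw[length(raw)])) raw <- raw[-length(raw)]
  raw
}

# Parse lines into a character matrix, erroring on ragged rows with the
# offending physical line number.
parse_delimited_lines <- function(lines, delimiter) {
  if (length(lines) == 0L) stop("empty input")
  if (nchar(delimiter) != 1L) stop("delimiter must be a single character")
  nf <- utils::count.fields(textConnection(lines), sep = delimiter,
                            quote = "\"", blank.lines.skip = FALSE,
                            comment.char = "")
  nf[is.na(nf)] <- 0L
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged row at line %d: %d field(s), expected %d",
                 bad, nf[bad], nf[1L]))
  }
  df <- utils::read.table(text = lines, sep = delimiter, quote = "\"",
                          colClasses = "character", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          na.strings = character(), blank.lines.skip = FALSE)
  as.matrix(df)
}

cell_as_number <- function(x) {
  suppressWarnings(as.numeric(x))
}

#' Read a delimited numeric data table
#'
#' The first column always contains row IDs; the remaining columns are
#' numeric features. Header presence is an explicit flag, never guessed.
#'
#' @param file path to a delimited text file (UTF-8).
#' @param delimiter single field-separator character (default comma).
#' @param header logical; if `TRUE` the first row holds feature names.
#' @param text optional character scalar/vector used instead of `file`.
#' @param missing policy for empty or non-numeric cells: `"error"` (default)
#'   aborts naming the cell; `"drop"` removes every affected row.
#' @return A [data_matrix].
#' @examples
#' read_data_table(text = "id,f1,f2\na,1,2\nb,3,4", header = TRUE)
#' @export
read_data_table <- function(file = NULL, delimiter = ",", header = FALSE,
                            text = NULL, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  lines <- split_input_lines(file, text)
  cells <- parse_delimited_lines(lines, delimiter)
  if (ncol(cells) < 2L) stop("a data table needs an ID column plus at least one feature column")
  if (header) {
    if (nrow(cells) < 2L) stop("no data rows below the header")
    feature_names <- cells[1L, -1L]
    cells <- cells[-1L, , drop = FALSE]
    line_no <- seq_len(nrow(cells)) + 1L
  } else {
    feature_names <- paste0("feature_", seq_len(ncol(cells) - 1L))
    line_no <- seq_len(nrow(cells))
  }
  row_ids <- cells[, 1L]
  dup <- duplicated(row_ids)
  if (any(dup)) stop(sprintf("duplicate row ID '%s'", row_ids[dup][1L]))
  num <- matrix(cell_as_number(cells[, -1L, drop = FALSE]),
                nrow = nrow(cells))
  bad <- !is.finite(num) | !nzchar(trimws(cells[, -1L, drop = FALSE]))
  if (any(bad)) {
    if (missing == "error") {
      ij <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf("non-numeric cell at line %d (row '%s'), feature '%s'",
                   line_no[ij[1L]], row_ids[ij[1L]], feature_names[ij[2L]]))
    }
    keep <- rowSums(bad) == 0L
    num <- num[keep, , drop = FALSE]
    row_ids <- row_ids[keep]
    if (nrow(num) == 0L) stop("all rows dropped by the missing-value policy")
  }
  data_matrix(num, row_ids = row_ids, feature_names = feature_names)
}

#' Read a delimited metadata table
#'
#' Same format as [read_data_table] but each column's type is inferred:
#' numeric when every non-empty cell parses as a number, categorical
#' otherwise (mixed columns fall back to categorical). Empty cells become
#' `NA`.
#'
#' @inheritParams read_data_table
#' @return A [metadata_table].
#' @export
read_metadata_table <- function(file = NULL, delimiter = ",", header = FALSE,
                                text = NULL) {
  lines <- split_input_lines(file, text)
  cells <- parse_delimited_lines(lines, delimiter)
  if (ncol(cells) < 2L) stop("a metadata table needs an ID column plus at least one column")
  if (header) {
    if (nrow(cells) < 2L) stop("no metadata rows below the header")
    feature_names <- cells[1L, -1L]
    cells <- cells[-1L, , drop = FALSE]
  } else {
    feature_names <- paste0("feature_", seq_len(ncol(cells) - 1L))
  }
  row_ids <- cells[, 1L]
  dup <- duplicated(row_ids)
  if (any(dup)) stop(sprintf("duplicate row ID '%s'", row_ids[dup][1L]))
  cols <- lapply(seq_len(ncol(cells) - 1L), function(j) {
    raw <- cells[, j + 1L]
    raw[!nzchar(trimws(raw))] <- NA_character_
    num <- cell_as_number(raw)
    present <- !is.na(raw)
    if (any(present) && all(is.finite(num[present]))) num else raw
  })
  names(cols) <- feature_names
  metadata_table(as.data.frame(cols, optional = TRUE,
                               stringsAsFactors = FALSE),
                 row_ids = row_ids, feature_names = feature_names)
}

#' Align a metadata table to the row order of a data matrix
#'
#' Metadata are matched to data rows through their IDs. Data rows without
#' metadata receive `NA` cells; metadata rows absent from the data are
#' dropped with a warning stating how many.
#'
#' @param data a [data_matrix].
#' @param meta a [metadata_table].
#' @return A [metadata_table] whose row order equals `data$row_ids`.
#' @export
join_metadata <- function(data, meta) {
  stopifnot(inherits(data, "data_matrix"), inherits(meta, "metadata_table"))
  idx <- match(data$row_ids, meta$row_ids)
  vals <- meta$values[idx, , drop = FALSE]
  dropped <- setdiff(meta$row_ids, data$row_ids)
  if (length(dropped) > 0L) {
    warning(sprintf("%d metadata row(s) without a matching data row were dropped",
                    length(dropped)))
  }
  metadata_table(vals, row_ids = data$row_ids,
                 feature_names = meta$feature_names)
}

quote_field <- function(x, delimiter) {
  needs <- grepl(delimiter, x, fixed = TRUE) | grepl("\"", x, fixed = TRUE) |
    grepl("\n", x, fixed = TRUE)
  x[needs] <- paste0("\"", gsub("\"", "\"\"", x[needs], fixed = TRUE), "\"")
  x
}

# %.17g survives a text round trip bit-exactly for doubles
format_number <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Write a data matrix as a delimited table
#'
#' @param x a [data_matrix].
#' @param file output path.
#' @param delimiter single separator character.
#' @param header logical; write the feature names as a first row.
#' @return The path, invisibly.
#' @export
write_data_table <- function(x, file, delimiter = ",", header = TRUE) {
  stopifnot(inherits(x, "data_matrix"))
  body <- vapply(seq_along(x$row_ids), function(i) {
    paste(c(quote_field(x$row_ids[i], delimiter),
            format_number(x$values[i, ])), collapse = delimiter)
  }, character(1L))
  lines <- body
  if (header) {
    lines <- c(paste(c("id", quote_field(x$feature_names, delimiter)),
                     collapse = delimiter), lines)
  }
  writeLines(lines, file, useBytes = TRUE)
  invisible(file)
}

#' Write a metadata table as a delimited table
#'
#' @param x a [metadata_table].
#' @inheritParams write_data_table
#' @return The path, invisibly.
#' @export
write_metadata_table <- function(x, file, delimiter = ",", header = TRUE) {
  stopifnot(inherits(x, "metadata_table"))
  body <- vapply(seq_along(x$row_ids), function(i) {
    cells <- vapply(x$values[i, , drop = FALSE], function(v) {
      if (is.numeric(v)) format_number(v) else {
        if (is.na(v)) "" else quote_field(v, delimiter)
      }
    }, character(1L))
    paste(c(quote_field(x$row_ids[i], delimiter), cells), collapse = delimiter)
  }, character(1L))
  lines <- body
  if (header) {
    lines <- c(paste(c("id", quote_field(x$feature_names, delimiter)),
                     collapse = delimiter), lines)
  }
  writeLines(lines, file, useBytes = TRUE)
  invisible(file)
}
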