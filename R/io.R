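# Delimited-text readers/writers. Layout contract: header row carries the
# wavenumber axis; an optional `sample_id` first column and an optional
# `label` last column are recognised by name; labels may instead live in a
# separate single-column file. Comma is the default delimiter, tab accepted.

#' Read a spectral dataset from a delimited text file
#'
#' The first row is the wavenumber axis. A first column named `sample_id`
#' and a column named `label` are treated as metadata; every other column
#' name must parse as a number (the wavenumber of that variable). Labels can
#' alternatively be supplied as a separate single-column text file (one label
#' per row, no header).
#'
#' @param path Path to the spectra table (CSV by default).
#' @param labels_path Optional path to a single-column label file.
#' @param sep Field delimiter: `","` (default) or `"\t"`.
#' @return A [spectral_dataset].
#' @export
read_dataset <- function(path, labels_path = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) != 1L)
    stop(sprintf("format error in '%s': ragged rows (field counts %s)",
                 path, paste(unique(nf), collapse = "/")))
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty dataset refused: no data rows in ", path)
  cols <- names(df)
  sample_ids <- NULL
  if (cols[1] == "sample_id") {
    sample_ids <- df[[1]]
    df <- df[, -1, drop = FALSE]
    cols <- names(df)
  }
  labels <- NULL
  if ("label" %in% cols) {
    labels <- df[["label"]]
    df <- df[, cols != "label", drop = FALSE]
    cols <- names(df)
  }
  wn <- suppressWarnings(as.numeric(cols))
  if (anyNA(wn))
    stop("header columns must be numeric wavenumbers; offending: ",
         paste(utils::head(cols[is.na(wn)], 3), collapse = ", "))
  mat <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad) > 0L)
      stop(sprintf("parse error in '%s': non-numeric intensity at row %d, column '%s'",
                   path, bad[1], cols[j]))
    mat[, j] <- v
  }
  if (!is.null(labels_path)) {
    if (!is.null(labels))
      stop("labels given both in the spectra table and in labels_path")
    labels <- readLines(labels_path, warn = FALSE)
    labels <- labels[nzchar(labels)]
  }
  if (is.null(labels))
    stop("no labels found: add a `label` column or pass labels_path")
  if (length(labels) != nrow(mat))
    stop(sprintf("consistency error: %d labels for %d spectra",
                 length(labels), nrow(mat)))
  spectral_dataset(mat, wn, labels, sample_ids)
}

#' Write a spectral dataset to a delimited text file
#'
#' Writes in the layout accepted by [read_dataset()] (`sample_id` column,
#' wavenumber-named intensity columns, trailing `label` column). Numbers are
#' written with 17 significant digits so that write-then-read reproduces the
#' dataset exactly.
#'
#' @param ds A [spectral_dataset].
#' @param path Output path.
#' @param sep Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (n_samples(ds) == 0L) stop("empty dataset refused")
  num <- function(x) formatC(x, digits = 17, format = "g")
  header <- c("sample_id", num(ds$wavenumbers), "label")
  body <- cbind(ds$sample_ids,
                matrix(num(ds$intensities), nrow = n_samples(ds)),
                as.character(ds$labels))
  lines <- c(paste(header, collapse = sep),
             apply(body, 1, paste, collapse = sep))
  ok <- tryCatch({
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con), add = TRUE)
    writeLines(lines, con, useBytes = FALSE)
    TRUE
  }, error = function(e) stop("I/O failure writing '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}
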