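# Tabular results with a parameter-metadata sidecar.

#' Construct a results table
#'
#' A plain data frame of per-cell / per-mitochondrion numbers plus a
#' metadata block recording every tunable parameter (and seed) used to
#' produce it, so any CSV on disk can be traced back to its settings.
#'
#' @param df data frame; the first column is treated as the row key.
#' @param metadata named list of parameters (must include every tunable
#'   used; a `seed` entry is conventional for simulated inputs).
#' @param source_ids optional character vector of valid keys (e.g. cell
#'   ids from the annotation set); when given, every row key must be in it.
#' @return object of class `ResultsTable` (a data frame subclass).
#' @export
results_table <- function(df, metadata = list(), source_ids = NULL) {
  df <- as.data.frame(df)
  if (!is.null(source_ids) && nrow(df) > 0) {
    keys <- as.character(df[[1]])
    bad <- setdiff(keys, as.character(source_ids))
    if (length(bad)) {
      stop("row key(s) not present in the source annotations: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(df, metadata = metadata,
            class = c("ResultsTable", "data.frame"))
}

#' Write a results table to CSV with a JSON metadata sidecar
#'
#' The CSV has one header row, UTF-8 encoding and `.` as decimal
#' separator; `<path>.json` holds the metadata block. No timestamps are
#' written, so identical inputs produce byte-identical files.
#'
#' @param table a `ResultsTable` (or plain data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  ok <- try(utils::write.csv(as.data.frame(table), path,
                             row.names = FALSE, fileEncoding = "UTF-8"),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("cannot write results at '", path, "': ",
         attr(ok, "condition")$message)
  }
  meta <- attr(table, "metadata")
  if (is.null(meta)) meta <- list()
  meta$software <- paste0("isletmito ",
                          as.character(utils::packageVersion("isletmito")))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return a `ResultsTable` with the sidecar metadata attached.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no results file at '", path, "'")
  df <- utils::read.csv(path, fileEncoding = "UTF-8",
                        check.names = FALSE)
  meta <- list()
  if (file.exists(.sidecar_path(path))) {
    meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  }
  results_table(df, metadata = meta)
}
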