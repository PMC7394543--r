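# Delimited-table IO with schema validation and run manifests.

#' Read a delimited sample table
#'
#' Accepts CSV or TSV, sniffing the delimiter from the header line, and
#' optionally validates against a schema before returning.
#'
#' @param path File path.
#' @param schema Optional schema for [validate_table()].
#' @return A tibble.
#' @export
read_sample_table <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- readLines(path, n = 1)
  delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (!is.null(schema)) validate_table(df, schema)
  df
}

#' Validate a table against a declared schema
#'
#' Collects every violation (missing columns, wrong types, duplicate keys,
#' non-finite numeric cells) and raises one aggregated error listing all of
#' them, rather than failing on the first.
#'
#' @param df Data frame to validate.
#' @param schema List with optional elements `columns` (named character
#'   vector column -> type, types `"numeric"` / `"character"` /
#'   `"integer"`), `key` (character vector of columns whose combination must
#'   be unique), `no_na` (columns that must be complete).
#' @return `df` invisibly when valid.
#' @export
validate_table <- function(df, schema) {
  problems <- character(0)
  if (!is.null(schema$columns)) {
    missing <- setdiff(names(schema$columns), names(df))
    if (length(missing)) {
      problems <- c(problems,
                    sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    }
    for (col in intersect(names(schema$columns), names(df))) {
      want <- schema$columns[[col]]
      ok <- switch(want,
                   numeric = is.numeric(df[[col]]),
                   integer = is.numeric(df[[col]]) &&
                     all(df[[col]] == floor(df[[col]]), na.rm = TRUE),
                   character = is.character(df[[col]]) || is.factor(df[[col]]),
                   TRUE)
      if (!ok) problems <- c(problems,
                             sprintf("column `%s` is not %s", col, want))
      if (want == "numeric" && is.numeric(df[[col]]) && any(!is.finite(df[[col]]) & !is.na(df[[col]]))) {
        problems <- c(problems, sprintf("column `%s` has non-finite values", col))
      }
    }
  }
  if (!is.null(schema$key) && all(schema$key %in% names(df))) {
    dup <- duplicated(df[, schema$key, drop = FALSE])
    if (any(dup)) {
      problems <- c(problems,
                    sprintf("duplicate key (%s) in %d row(s)",
                            paste(schema$key, collapse = ", "), sum(dup)))
    }
  }
  for (col in intersect(schema$no_na %||% character(0), names(df))) {
    if (anyNA(df[[col]])) {
      problems <- c(problems, sprintf("column `%s` has missing values", col))
    }
  }
  if (length(problems)) {
    abort(paste0("Table validation failed:\n",
                 paste0("  - ", problems, collapse = "\n")))
  }
  invisible(df)
}

#' Write a run manifest
#'
#' Records the resolved configuration, seed, package version and the list of
#' artifacts a pipeline run produced, as JSON — enough to reproduce the run.
#'
#' @param path Output JSON path.
#' @param config Named list of the resolved configuration.
#' @param outputs Character vector of artifact paths written.
#' @return `path` invisibly.
#' @export
write_run_manifest <- function(path, config, outputs) {
  manifest <- list(
    package = "twinlipids",
    version = as.character(utils::packageVersion("twinlipids")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config,
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
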