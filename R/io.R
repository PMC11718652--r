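# Readers, writers and configuration ---------------------------------------

io_error <- function(type, msg) {
  stop(structure(
    list(message = msg, call = NULL),
    class = c(paste0("hvs_", type, "_error"), "hvs_io_error",
              "error", "condition")
  ))
}

#' Read a compound library from .smi or CSV
#'
#' `.smi`: one record per line, `SMILES[whitespace]ID`, UTF-8; blank
#' lines and lines starting with `#` are skipped. CSV: a named SMILES
#' column and an optional id column. Records missing an id get
#' `row_<n>` (0-based source position). Duplicate ids are rejected.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"smi"`, or `"csv"`.
#' @param smiles_col,id_col CSV column names (id optional).
#' @return A data.frame with columns `id`, `smiles`, `row_number`
#'   (0-based source position), in file order.
#' @export
read_library <- function(path, format = c("auto", "smi", "csv"),
                         smiles_col = "smiles", id_col = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    io_error("input", sprintf("library file not found: %s", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else
      "smi"
  }
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
    if (length(keep) == 0L) {
      io_error("input", sprintf("empty library file: %s", path))
    }
    parts <- strsplit(trimws(lines[keep]), "\\s+")
    smiles <- vapply(parts, `[[`, character(1), 1L)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2L) parts[[i]][2L] else
        paste0("row_", keep[i] - 1L)
    }, character(1))
    row_number <- keep - 1L
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(df) == 0L) {
      io_error("input", sprintf("empty library file: %s", path))
    }
    if (!smiles_col %in% names(df)) {
      io_error("input", sprintf(
        "missing SMILES column '%s' (found: %s)", smiles_col,
        paste(names(df), collapse = ", ")))
    }
    smiles <- as.character(df[[smiles_col]])
    ids <- if (!is.null(id_col)) {
      if (!id_col %in% names(df)) {
        io_error("input", sprintf("missing id column '%s'", id_col))
      }
      as.character(df[[id_col]])
    } else {
      paste0("row_", seq_len(nrow(df)) - 1L)
    }
    row_number <- seq_len(nrow(df)) - 1L
  }
  dup <- which(duplicated(ids))
  if (length(dup) > 0L) {
    first <- match(ids[dup[1]], ids)
    io_error("input", sprintf(
      "duplicate id '%s' at rows %d and %d", ids[dup[1]],
      row_number[first], row_number[dup[1]]))
  }
  data.frame(id = ids, smiles = smiles, row_number = row_number,
             row.names = NULL)
}

#' Write cluster summaries as CSV
#'
#' Header `cluster,count,min,max`; values at input precision.
#' [read_summaries()] inverts it exactly.
#'
#' @param summaries A data.frame with columns `cluster`, `count`,
#'   `min`, `max` (non-empty).
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_summaries <- function(summaries, path) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) == 0L) {
    io_error("input", "refusing to write an empty summary table")
  }
  if (!all(c("cluster", "count", "min", "max") %in% names(summaries))) {
    io_error("input", "summaries need columns cluster, count, min, max")
  }
  utils::write.csv(summaries[, c("cluster", "count", "min", "max")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cluster-summary CSV
#'
#' Reads the `cluster,count,min,max` schema. Numeric fields may contain
#' internal spaces as thousands separators (as large screening tables
#' are often typeset); they are stripped before conversion.
#'
#' @param path CSV path.
#' @return A data.frame (class `cluster_summary`) with integer
#'   `cluster`, `count` and numeric `min`, `max`.
#' @export
read_summaries <- function(path) {
  if (!file.exists(path)) {
    io_error("input", sprintf("summary file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("cluster", "count", "min", "max")
  if (!all(need %in% names(df))) {
    io_error("input", sprintf("summary file must have columns %s",
                              paste(need, collapse = ",")))
  }
  strip <- function(x) gsub("[ \u00a0\u2009]", "", x)
  out <- data.frame(
    cluster = as.integer(strip(df$cluster)),
    count = as.integer(strip(df$count)),
    min = as.numeric(strip(df$min)),
    max = as.numeric(strip(df$max))
  )
  if (anyNA(out)) {
    io_error("input", sprintf("non-numeric fields in summary file: %s",
                              path))
  }
  class(out) <- c("cluster_summary", "data.frame")
  out
}

#' Write compounds as a .smi file
#'
#' One `SMILES ID` record per line.
#'
#' @param records Data.frame with `id` and `smiles` columns.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_smi <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("id", "smiles") %in% names(records)))
  writeLines(paste(records$smiles, records$id), path)
  invisible(path)
}

#' Load a screening configuration from JSON
#'
#' Fills defaults (radius 2, 2048 bits, elbow scan over k 1-20, 10
#' restarts); `seed` is mandatory and unknown keys are rejected, so a
#' config file can never silently mean something else.
#'
#' @param path Path to a JSON object.
#' @return A [screen_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    io_error("config", sprintf("config file not found: %s", path))
  }
  raw <- tryCatch(jsonlite::fromJSON(path), error = function(e) {
    io_error("config", sprintf("invalid JSON in %s: %s", path,
                               conditionMessage(e)))
  })
  if (!is.list(raw)) io_error("config", "config must be a JSON object")
  known <- c("seed", "radius", "n_bits", "k", "k_range", "n_restarts")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    io_error("config", sprintf("unknown config key(s): %s",
                               paste(unknown, collapse = ", ")))
  }
  if (is.null(raw$seed)) {
    io_error("config", "config key 'seed' is required")
  }
  tryCatch(
    screen_config(
      seed = raw$seed,
      radius = raw$radius %||% 2L,
      n_bits = raw$n_bits %||% 2048L,
      k = raw$k,
      k_range = raw$k_range %||% c(1L, 20L),
      n_restarts = raw$n_restarts %||% 10L
    ),
    error = function(e) io_error("config", conditionMessage(e))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to a bundled example data file
#'
#' The package ships two reference cluster-statistic tables
#' (`morgan_cluster_stats.csv`, `pharm_cluster_stats.csv`) in the
#' `cluster,count,min,max` schema, summarizing K-Means clusterings of
#' Morgan and pharmacophore Tanimoto profiles from a full-scale screen
#' of a ~1.048M-compound drug-like library (20 and 17 clusters).
#'
#' @param file File name under `extdata`; empty lists the files.
#' @return Absolute path(s).
#' @export
hvs_example_file <- function(file = "") {
  if (nzchar(file)) {
    system.file("extdata", file, package = "hybridvs", mustWork = TRUE)
  } else {
    list.files(system.file("extdata", package = "hybridvs"))
  }
}
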