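# Canonical trace file dialect: UTF-8, '#'-prefixed "key: value" metadata
# header, then a "time_s,value" CSV body. Potentiostat vendors export wildly
# different formats, so the package defines one documented dialect and all
# tooling speaks it.

TRACE_FLOAT_FMT <- "%.12g"   # fixed formatting => byte-stable writes

#' Write an experiment record to a trace file
#'
#' Serializes the record in the package's canonical delimited-text dialect:
#' `#`-prefixed `key: value` metadata lines (fixed key order), a
#' `time_s,value` header, then one CSV row per sample with fixed float
#' formatting. Writing the same record twice produces byte-identical files.
#'
#' @param record An [experiment_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_trace()]
#' @export
write_trace <- function(record, path) {
  if (!inherits(record, "experiment_record")) {
    stop("`record` must be an experiment_record", call. = FALSE)
  }
  ts <- record$trace
  meta <- c(
    sprintf("# channel_kind: %s", ts$channel_kind),
    sprintf("# unit: %s", ts$unit),
    sprintf("# salt_name: %s", record$salt_name),
    if (!is.null(record$addition_time)) {
      sprintf("# addition_time_s: %s",
              sprintf(TRACE_FLOAT_FMT, record$addition_time))
    },
    sprintf("# addition_volume_ul: %s",
            sprintf(TRACE_FLOAT_FMT, record$addition_volume_ul)),
    sprintf("# addition_concentration_M: %s",
            sprintf(TRACE_FLOAT_FMT, record$addition_concentration)),
    sprintf("# is_control: %s", if (record$is_control) "true" else "false"),
    sprintf("# n_plants: %d", record$n_plants),
    sprintf("# plant_age_days: %d", record$plant_age_days)
  )
  body <- sprintf(paste0(TRACE_FLOAT_FMT, ",", TRACE_FLOAT_FMT),
                  ts$times, ts$values)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta, "time_s,value", body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read an experiment record from a trace file
#'
#' Parses the canonical trace dialect written by [write_trace()]. The reader
#' validates rather than repairs: non-monotone or duplicated timestamps,
#' malformed rows and missing mandatory metadata (`channel_kind`, `unit`) are
#' errors that name the offending line. Samples are never reordered.
#'
#' @param path Path to a trace file.
#' @return An [experiment_record()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("trace file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  meta <- list()
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    m <- regmatches(lines[i],
                    regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)\\s*$", lines[i]))[[1L]]
    if (length(m) != 3L) {
      stop(sprintf("line %d: malformed metadata line: %s", i, lines[i]),
           call. = FALSE)
    }
    meta[[m[2L]]] <- m[3L]
    i <- i + 1L
  }
  if (is.null(meta$channel_kind)) {
    stop("missing mandatory metadata key 'channel_kind'", call. = FALSE)
  }
  if (is.null(meta$unit)) {
    stop("missing mandatory metadata key 'unit'", call. = FALSE)
  }
  expected_unit <- CHANNEL_UNITS[meta$channel_kind]
  if (is.na(expected_unit)) {
    stop(sprintf("unknown channel_kind '%s'", meta$channel_kind), call. = FALSE)
  }
  if (meta$unit != expected_unit) {
    stop(sprintf("unit '%s' inconsistent with channel_kind '%s' (expected '%s')",
                 meta$unit, meta$channel_kind, expected_unit), call. = FALSE)
  }
  if (i > length(lines) || lines[i] != "time_s,value") {
    stop(sprintf("line %d: expected column header 'time_s,value'", i),
         call. = FALSE)
  }
  body_start <- i + 1L
  body <- lines[seq.int(body_start, length.out = length(lines) - body_start + 1L)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("trace file has no data rows", call. = FALSE)
  parts <- strsplit(body, ",", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    bad <- which(nfield != 2L)[1L]
    stop(sprintf("line %d: malformed data row: %s", body_start + bad - 1L,
                 body[bad]), call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 2L, byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1L, any))[1L]
    stop(sprintf("line %d: non-numeric data row: %s", body_start + bad - 1L,
                 body[bad]), call. = FALSE)
  }
  times <- mat[, 1L]
  if (length(times) > 1L && any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop(sprintf("line %d: timestamp not strictly increasing: %s",
                 body_start + bad - 1L, body[bad]), call. = FALSE)
  }
  ts <- time_series(times, mat[, 2L], meta$channel_kind)
  experiment_record(
    trace = ts,
    salt_name = meta$salt_name %||% "unknown",
    addition_time = if (!is.null(meta$addition_time_s))
      as.numeric(meta$addition_time_s),
    addition_volume_ul = as.numeric(meta$addition_volume_ul %||% 30),
    addition_concentration = as.numeric(meta$addition_concentration_M %||% 0.1),
    is_control = identical(meta$is_control, "true"),
    n_plants = as.integer(meta$n_plants %||% 0L),
    plant_age_days = as.integer(meta$plant_age_days %||% 0L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an experiment manifest
#'
#' A manifest is a CSV with columns `path`, `salt_name`, `role`
#' (`plant` or `control`) listing the trace files of one batch run. Relative
#' paths are resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A data.frame with columns `path` (as listed), `salt_name`,
#'   `role`, and `resolved_path` (absolute-or-relative path usable from the
#'   working directory). Downstream tables report the listed `path` so
#'   outputs do not depend on where the manifest happens to live.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "salt_name", "role")
  if (!all(need %in% names(df))) {
    stop(sprintf("manifest must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("manifest is empty", call. = FALSE)
  if (!all(df$role %in% c("plant", "control"))) {
    stop("manifest role must be 'plant' or 'control'", call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$resolved_path <- df$path
  df$resolved_path[rel] <- file.path(dirname(path), df$path[rel])
  df
}
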