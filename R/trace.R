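#' Glucose trace objects
#'
#' A `glucose_trace` holds one participant's timestamped CGM readings,
#' partitioned into sensor blocks (one block per sensor wear). Readings are
#' kept on the irregular native grid; nothing is interpolated.
#'
#' @param participant_id Opaque participant identifier (scalar character).
#' @param readings A data frame with columns `timestamp` (POSIXct, minute
#'   resolution), `glucose` (mmol/L) and `block_id` (integer sensor-block
#'   index).
#' @param warmup_trimmed Logical; `TRUE` once the first 24 h of each block
#'   have been removed (see [merge_blocks()]).
#'
#' @return An object of class `glucose_trace`: a list with elements
#'   `participant_id`, `readings` (tibble sorted by block then timestamp)
#'   and `warmup_trimmed`.
#' @export
glucose_trace <- function(participant_id, readings, warmup_trimmed = FALSE) {
  stopifnot(is.character(participant_id), length(participant_id) == 1)
  readings <- tibble::as_tibble(readings)
  required <- c("timestamp", "glucose", "block_id")
  missing_cols <- setdiff(required, names(readings))
  if (length(missing_cols) > 0) {
    stop("trace readings missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!inherits(readings$timestamp, "POSIXct")) {
    stop("timestamp column must be POSIXct", call. = FALSE)
  }
  readings$block_id <- as.integer(readings$block_id)
  readings <- readings[order(readings$timestamp), required]
  validate_readings(readings, participant_id)
  structure(
    list(participant_id = participant_id,
         readings = readings,
         warmup_trimmed = isTRUE(warmup_trimmed)),
    class = "glucose_trace"
  )
}

validate_readings <- function(readings, participant_id) {
  if (nrow(readings) == 0) return(invisible(readings))
  if (any(!is.finite(readings$glucose)) ||
      any(readings$glucose <= 0) || any(readings$glucose >= 40)) {
    stop("participant ", participant_id,
         ": glucose values must lie in (0, 40) mmol/L", call. = FALSE)
  }
  # block ids must form contiguous runs once sorted by time
  runs <- rle(readings$block_id)$values
  if (anyDuplicated(runs)) {
    stop("participant ", participant_id,
         ": block_ids do not form contiguous runs in time ",
         "(overlapping or interleaved sensor blocks)", call. = FALSE)
  }
  for (b in unique(readings$block_id)) {
    ts <- readings$timestamp[readings$block_id == b]
    if (any(diff(as.numeric(ts)) <= 0)) {
      stop("participant ", participant_id, ": non-monotone timestamps ",
           "within block ", b, call. = FALSE)
    }
  }
  invisible(readings)
}

#' @export
print.glucose_trace <- function(x, ...) {
  n <- nrow(x$readings)
  cat("<glucose_trace> participant ", x$participant_id, "\n", sep = "")
  cat("  readings: ", n, " in ", length(unique(x$readings$block_id)),
      " block(s)", if (x$warmup_trimmed) "  [warm-up trimmed]", "\n",
      sep = "")
  if (n > 0) {
    cat("  span: ", format(x$readings$timestamp[1]), " to ",
        format(x$readings$timestamp[n]), "\n", sep = "")
  }
  invisible(x)
}

#' Read a CGM trace from CSV
#'
#' Supports two dialects. The canonical format has a header
#' `participant_id,timestamp,glucose_mmol_l,block_id` with ISO-8601
#' timestamps. The `libre` dialect accepts a Freestyle Libre-style export:
#' an optional metadata preamble line, columns `"Device Timestamp"` and
#' `"Historic Glucose mmol/L"` (record type 0 rows only), with scan and
#' note rows ignored. If only a `"Historic Glucose mg/dL"` column is
#' present, values are divided by 18.016. Blocks are taken from the
#' `"Serial Number"` column when present (one block per sensor), otherwise
#' a single block is assumed.
#'
#' @param path Path to the CSV file.
#' @param dialect `"canonical"` or `"libre"`.
#' @param participant_id Identifier override; defaults to the file's
#'   `participant_id` column (canonical) or the file name (libre).
#' @return A [glucose_trace()].
#' @export
read_trace_csv <- function(path, dialect = c("canonical", "libre"),
                           participant_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "canonical") {
    read_trace_canonical(path, participant_id)
  } else {
    read_trace_libre(path, participant_id)
  }
}

read_trace_canonical <- function(path, participant_id) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) stop("empty trace file: ", path, call. = FALSE)
  required <- c("participant_id", "timestamp", "glucose_mmol_l", "block_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("canonical trace CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pid <- participant_id %||% df$participant_id[1]
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (any(is.na(ts))) stop("unparseable timestamp in ", path, call. = FALSE)
  glucose_trace(pid, tibble::tibble(
    timestamp = ts,
    glucose = as.numeric(df$glucose_mmol_l),
    block_id = as.integer(df$block_id)
  ))
}

read_trace_libre <- function(path, participant_id) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(lines))) {
    stop("empty trace file: ", path, call. = FALSE)
  }
  header_at <- grep("Device Timestamp", lines)[1]
  if (is.na(header_at)) {
    stop("libre trace CSV missing column: Device Timestamp", call. = FALSE)
  }
  df <- utils::read.csv(text = paste(lines[header_at:length(lines)],
                                     collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  mmol_col <- "Historic Glucose mmol/L"
  mgdl_col <- "Historic Glucose mg/dL"
  has_mmol <- mmol_col %in% names(df)
  has_mgdl <- mgdl_col %in% names(df)
  if (!has_mmol && !has_mgdl) {
    stop("libre trace CSV missing column: ", mmol_col, call. = FALSE)
  }
  if ("Record Type" %in% names(df)) {
    df <- df[df[["Record Type"]] %in% c(0, "0"), , drop = FALSE]
  }
  glucose <- if (has_mmol) as.numeric(df[[mmol_col]]) else
    as.numeric(df[[mgdl_col]]) / 18.016
  keep <- !is.na(glucose)
  df <- df[keep, , drop = FALSE]
  glucose <- glucose[keep]
  if (nrow(df) == 0) stop("no historic glucose rows in ", path, call. = FALSE)
  ts <- as.POSIXct(df[["Device Timestamp"]], tz = "UTC",
                   tryFormats = c("%d-%m-%Y %H:%M", "%m-%d-%Y %H:%M",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%dT%H:%M:%S",
                                  "%Y-%m-%d %H:%M:%S"))
  if (any(is.na(ts))) stop("unparseable Device Timestamp in ", path,
                           call. = FALSE)
  block_id <- if ("Serial Number" %in% names(df)) {
    match(df[["Serial Number"]], unique(df[["Serial Number"]][order(ts)]))
  } else rep(1L, nrow(df))
  pid <- participant_id %||%
    sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  glucose_trace(pid, tibble::tibble(timestamp = ts, glucose = glucose,
                                    block_id = as.integer(block_id)))
}

#' Write a trace in the canonical CSV format
#'
#' @param trace A [glucose_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "glucose_trace"))
  df <- tibble::tibble(
    participant_id = trace$participant_id,
    timestamp = format(trace$readings$timestamp, "%Y-%m-%dT%H:%M:%S"),
    glucose_mmol_l = trace$readings$glucose,
    block_id = trace$readings$block_id
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Trim warm-up periods and merge sensor blocks
#'
#' Removes the first `warmup_hours` (default 24 h) of every sensor block --
#' first-day flash-sensor readings run systematically low -- and
#' concatenates the remainder into one logically continuous series.
#' Trimming is idempotent: a trace whose `warmup_trimmed` flag is already
#' set is returned unchanged. Blocks whose time ranges overlap raise an
#' error (two sensors worn at once cannot be merged).
#'
#' @param trace A [glucose_trace()].
#' @param warmup_hours Hours removed from the start of each block.
#' @return A [glucose_trace()] with `warmup_trimmed = TRUE`.
#' @export
merge_blocks <- function(trace, warmup_hours = 24) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (trace$warmup_trimmed) return(trace)
  r <- trace$readings
  if (nrow(r) > 0) {
    blocks <- unique(r$block_id)
    if (length(blocks) > 1) {
      rng <- lapply(blocks, function(b) range(r$timestamp[r$block_id == b]))
      ord <- order(vapply(rng, function(x) as.numeric(x[1]), 0))
      rng <- rng[ord]
      for (i in seq_len(length(rng) - 1)) {
        if (rng[[i]][2] >= rng[[i + 1]][1]) {
          stop("participant ", trace$participant_id,
               ": sensor blocks overlap in time", call. = FALSE)
        }
      }
    }
    keep <- rep(TRUE, nrow(r))
    for (b in blocks) {
      idx <- which(r$block_id == b)
      start <- r$timestamp[idx[1]]
      keep[idx] <- as.numeric(r$timestamp[idx] - start, units = "hours") >=
        warmup_hours
    }
    r <- r[keep, , drop = FALSE]
  }
  out <- trace
  out$readings <- r
  out$warmup_trimmed <- TRUE
  out
}

#' Assess whether a trace carries enough data
#'
#' Covered time is the sum of inter-reading intervals, each capped at
#' `gap_cap` hours (a flash sensor stores about 8 h of readings, so longer
#' gaps are true data loss, not slow sampling). A trace is usable when the
#' covered time reaches `min_covered_hours`.
#'
#' @param trace A warm-up-trimmed [glucose_trace()].
#' @param min_covered_hours Minimum covered time (default 72 h).
#' @param gap_cap Per-interval cap in hours (default 8).
#' @return A one-row tibble: `total_span`, `covered_time`, `n_readings`,
#'   `n_blocks`, `usable`.
#' @export
assess_quality <- function(trace, min_covered_hours = 72, gap_cap = 8) {
  stopifnot(inherits(trace, "glucose_trace"))
  r <- trace$readings
  n <- nrow(r)
  if (n < 2) {
    return(tibble::tibble(total_span = 0, covered_time = 0, n_readings = n,
                          n_blocks = length(unique(r$block_id)),
                          usable = FALSE))
  }
  gaps <- diff(as.numeric(r$timestamp)) / 3600
  covered <- sum(pmin(gaps, gap_cap))
  tibble::tibble(
    total_span = as.numeric(r$timestamp[n] - r$timestamp[1], units = "hours"),
    covered_time = covered,
    n_readings = n,
    n_blocks = length(unique(r$block_id)),
    usable = covered >= min_covered_hours
  )
}

#' Per-reading duration weights for an irregular series
#'
#' Reading `i` carries weight `min(t[i+1] - t[i], gap_cap)` hours; the last
#' reading carries the median inter-reading interval (a single-reading
#' trace carries a nominal 15 minutes). These weights make "proportion of
#' time" statistics well defined on the irregular grid without
#' interpolation.
#'
#' @param trace A sorted [glucose_trace()].
#' @param gap_cap Per-interval cap in hours.
#' @return Numeric vector of per-reading durations in hours.
#' @export
interval_weights <- function(trace, gap_cap = 8) {
  stopifnot(inherits(trace, "glucose_trace"))
  n <- nrow(trace$readings)
  if (n == 0) return(numeric(0))
  if (n == 1) return(0.25)
  gaps <- diff(as.numeric(trace$readings$timestamp)) / 3600
  w <- pmin(gaps, gap_cap)
  c(w, min(stats::median(gaps), gap_cap))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
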