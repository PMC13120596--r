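#' Read and write two-channel distance streams
#'
#' Streams are CSV files with header
#' \code{timestamp_ms,torso_mm,head_mm}: integer milliseconds since
#' epoch and integer millimetre distances. Reading validates the header,
#' flags malformed (non-numeric or missing) cells and non-monotone
#' timestamps with the offending file line number, and accepts an empty
#' body. Writing then reading reproduces the values exactly.
#'
#' @param path File path.
#' @param stream Data frame with the three stream columns.
#' @return \code{read_stream}: the stream data frame.
#' @export
read_stream <- function(path) {
  read_checked_csv(path, c("timestamp_ms", "torso_mm", "head_mm"))
}

#' @rdname read_stream
#' @export
write_stream <- function(stream, path) {
  utils::write.csv(stream[c("timestamp_ms", "torso_mm", "head_mm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write transition-event logs
#'
#' Event logs are CSV files with header \code{timestamp_ms,state},
#' where state is one of sit, stand, away. The same validation rules as
#' \code{\link{read_stream}} apply.
#'
#' @param path File path.
#' @param events Data frame with columns \code{timestamp_ms},
#'   \code{state}.
#' @return \code{read_events}: the event data frame.
#' @export
read_events <- function(path) {
  out <- read_checked_csv(path, c("timestamp_ms", "state"),
                          numeric_cols = "timestamp_ms")
  bad <- !out$state %in% posture_states()
  if (any(bad))
    stop(sprintf("unknown state '%s' at line %d of %s",
                 out$state[which(bad)[1]], which(bad)[1] + 1L, path),
         call. = FALSE)
  out
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  utils::write.csv(events[c("timestamp_ms", "state")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write bout tables
#'
#' Bout CSVs carry \code{state,start_ms,end_ms,duration_s}.
#'
#' @param path File path.
#' @param bouts Bout table as from \code{\link{bouts_from_events}}.
#' @return \code{read_bouts}: the bout data frame.
#' @export
read_bouts <- function(path) {
  read_checked_csv(path, c("state", "start_ms", "end_ms", "duration_s"),
                   numeric_cols = c("start_ms", "end_ms", "duration_s"),
                   monotone_col = NULL)
}

#' @rdname read_bouts
#' @export
write_bouts <- function(bouts, path) {
  utils::write.csv(bouts[c("state", "start_ms", "end_ms", "duration_s")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Shared CSV reader: header check, per-cell numeric validation with line
# numbers (line 1 is the header), strict timestamp monotonicity.
read_checked_csv <- function(path, columns, numeric_cols = columns,
                             monotone_col = "timestamp_ms") {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  missing <- setdiff(columns, names(raw))
  if (length(missing) > 0L)
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  raw <- raw[columns]
  for (col in intersect(numeric_cols, columns)) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0L)
      stop(sprintf("malformed value '%s' in column %s at line %d of %s",
                   raw[[col]][bad[1]], col, bad[1] + 1L, path),
           call. = FALSE)
    raw[[col]] <- vals
  }
  if (!is.null(monotone_col) && monotone_col %in% columns &&
      nrow(raw) > 1L) {
    bad <- which(diff(raw[[monotone_col]]) <= 0)
    if (length(bad) > 0L)
      stop(sprintf("non-increasing %s at line %d of %s",
                   monotone_col, bad[1] + 2L, path), call. = FALSE)
  }
  raw
}
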