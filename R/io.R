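# Delimited-text I/O for recordings, event logs, tracks, and result tables.
# Canonical on-disk form: UTF-8 CSV with a mandatory header row; session
# metadata rides in leading '# key: value' comment lines; times are decimal
# seconds throughout.

new_raw_recording <- function(time_s, f465, f405, sampling_rate_hz,
                              sensor = "GCaMP6s", session = NULL) {
  stopifnot(length(time_s) == length(f465), length(f465) == length(f405))
  rec <- list(time_s = time_s, f465 = f465, f405 = f405,
              sampling_rate_hz = sampling_rate_hz, sensor = sensor,
              session = session)
  class(rec) <- "raw_recording"
  rec
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples @ %.4g Hz, sensor %s\n",
              length(x$time_s), x$sampling_rate_hz, x$sensor))
  if (!is.null(x$session))
    cat("  session:", paste(names(x$session), unlist(x$session),
                            sep = "=", collapse = " "), "\n")
  invisible(x)
}

new_event_log <- function(df) {
  stopifnot(all(c("timestamp_s", "label") %in% names(df)))
  if (!"metadata" %in% names(df)) df$metadata <- ""
  if (is.unsorted(df$timestamp_s)) {
    message("event log was unsorted; sorting by timestamp")
    df <- df[order(df$timestamp_s), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("event_log", "data.frame")
  df
}

new_track_session <- function(df, arena, rate_hz) {
  stopifnot(all(c("t_s", "x_cm", "y_cm") %in% names(df)))
  if (is.unsorted(df$t_s, strictly = TRUE))
    stop("track times must be strictly increasing")
  attr(df, "arena") <- arena
  attr(df, "rate_hz") <- rate_hz
  class(df) <- c("track_session", "data.frame")
  df
}

write_meta_header <- function(con, meta) {
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, as.character(meta[[nm]])), con)
}

read_meta_header <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  meta
}

#' Write / read a dual-channel recording as CSV
#'
#' Long-format CSV with columns \code{time_s,f465,f405}; sampling rate, sensor
#' and session labels are stored as leading \code{# key: value} comment lines
#' so that \code{write_recording} followed by \code{read_recording} is an
#' identity up to 1e-9.
#'
#' @param rec a \code{raw_recording}.
#' @param path output/input file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(sampling_rate_hz = format(rec$sampling_rate_hz, digits = 15),
                 sensor = rec$sensor), rec$session)
  write_meta_header(con, meta)
  df <- data.frame(time_s = rec$time_s, f465 = rec$f465, f405 = rec$f405)
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param schema named list mapping the expected roles \code{time},
#'   \code{f465}, \code{f405} to column names in the file.
#' @param na_policy \code{"error"} (default) to reject non-finite samples,
#'   \code{"drop"} to remove those rows.
#' @export
read_recording <- function(path, schema = list(time = "time_s",
                                               f465 = "f465", f405 = "f405"),
                           na_policy = c("error", "drop")) {
  na_policy <- match.arg(na_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_meta_header(path)
  df <- read.csv(path, comment.char = "#")
  for (role in c("time", "f465", "f405"))
    if (!schema[[role]] %in% names(df))
      stop("missing column: ", schema[[role]])
  time_s <- df[[schema$time]]
  f465 <- df[[schema$f465]]
  f405 <- df[[schema$f405]]
  ok <- is.finite(time_s) & is.finite(f465) & is.finite(f405)
  if (!all(ok)) {
    if (na_policy == "error")
      stop(sum(!ok), " rows with non-finite values (na_policy = 'error')")
    time_s <- time_s[ok]; f465 <- f465[ok]; f405 <- f405[ok]
  }
  if (any(bad <- diff(time_s) <= 0))
    stop("time column not strictly increasing at index ", which(bad)[1] + 1L)
  fs <- as.numeric(meta$sampling_rate_hz)
  if (length(fs) == 1 && is.finite(fs) && length(time_s) > 2) {
    mdt <- median(diff(time_s))
    if (abs(mdt - 1 / fs) > 0.01 / fs)
      stop("median inter-sample interval deviates >1% from 1/sampling_rate_hz")
  }
  session <- meta[setdiff(names(meta), c("sampling_rate_hz", "sensor"))]
  if (length(session) == 0) session <- NULL
  new_raw_recording(time_s, f465, f405, fs,
                    sensor = if (is.null(meta$sensor)) "GCaMP6s" else
                      meta$sensor,
                    session = session)
}

#' Write / read behavioral event logs
#'
#' CSV with columns \code{timestamp_s,label,metadata}. An empty file (header
#' only) loads as an empty log; unsorted timestamps are sorted on load with a
#' notice.
#'
#' @param log an \code{event_log}.
#' @param path file path.
#' @param span optional c(lo, hi); events outside error out when supplied.
#' @export
write_events <- function(log, path) {
  write.csv(as.data.frame(unclass(log)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, span = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, colClasses = c(timestamp_s = "numeric",
                                      label = "character",
                                      metadata = "character"))
  if (nrow(df) == 0)
    return(new_event_log(data.frame(timestamp_s = numeric(0),
                                    label = character(0),
                                    metadata = character(0))))
  log <- new_event_log(df)
  if (!is.null(span) && any(log$timestamp_s < span[1] |
                              log$timestamp_s > span[2]))
    stop("event timestamps fall outside the recording span")
  log
}

#' Write / read a position track
#'
#' CSV with columns \code{t_s,x_cm,y_cm}; the track rate is stored as a
#' comment line. On load, positions are validated against the arena bounds.
#'
#' @param track a \code{track_session}.
#' @param path file path.
#' @param arena the \code{\link{behavior_arena}} the track belongs to.
#' @export
write_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_meta_header(con, list(rate_hz = format(attr(track, "rate_hz"),
                                               digits = 15)))
  write.csv(format(as.data.frame(unclass(track))[c("t_s", "x_cm", "y_cm")],
                   digits = 15, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path, arena) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_meta_header(path)
  df <- read.csv(path, comment.char = "#")
  out <- df$x_cm < 0 | df$x_cm > arena$width_cm |
    df$y_cm < 0 | df$y_cm > arena$height_cm
  if (any(out))
    stop(sum(out), " track rows fall outside the arena bounds")
  new_track_session(df, arena = arena,
                    rate_hz = as.numeric(meta$rate_hz))
}

#' Write a result table as headered CSV with fixed column order
#' @param records a data frame.
#' @param path file path.
#' @export
write_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write simulation ground truth as a JSON sidecar
#' @param truth ground-truth list from \code{\link{simulate_recording}}.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  truth$params <- NULL
  truth$artifact <- NULL # full-length trace; regenerate from seed instead
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
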