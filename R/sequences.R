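#' Behavioral event sequences
#'
#' A behavioral sequence is the ordered series of display postures one focal
#' individual performed inside a fixed observation window (300 s by
#' default, the classical five-minute focal sample). Batches of sequences
#' are kept in one long tibble with columns `subject_id`, `t` (seconds from
#' window start), `posture`, and `span` (recorded observation length in
#' seconds, constant within a subject).
#'
#' @param subject_id Single id string.
#' @param t Numeric vector of event times, seconds from window start,
#'   strictly increasing, in `[0, window_length)`.
#' @param posture Character vector of posture codes, same length as `t`.
#' @param repertoire An [repertoire()] the codes must belong to.
#' @param window_length Window length in seconds (default 300).
#' @param span Recorded observation span in seconds. Defaults to the time
#'   of the last event; pass the true recording length when known so that
#'   [filter_complete()] can tell full five-minute samples from
#'   interrupted ones.
#'
#' @return A tibble with columns `subject_id`, `t`, `posture`, `span`.
#' @examples
#' behavior_sequence("f1", c(0, 10, 20), c("HF", "WS", "HF"), span = 300)
#' @export
behavior_sequence <- function(subject_id, t, posture,
                              repertoire = default_repertoire(),
                              window_length = 300,
                              span = NULL) {
  if (length(t) != length(posture)) {
    abort("`t` and `posture` must have the same length.")
  }
  if (length(t) < 1) {
    abort("A behavioral sequence needs at least one event.")
  }
  if (anyNA(t) || anyNA(posture)) {
    abort("Event times and postures must not be missing.")
  }
  if (is.unsorted(t, strictly = TRUE)) {
    abort(paste0("Event times for '", subject_id, "' must be strictly increasing."))
  }
  if (any(t < 0) || any(t >= window_length)) {
    abort(paste0(
      "Event times for '", subject_id, "' must lie in [0, ",
      window_length, ")."
    ))
  }
  bad <- setdiff(unique(posture), repertoire$label)
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown posture code(s) for '", subject_id, "': ",
      paste(bad, collapse = ", ")
    ))
  }
  span <- if (is.null(span)) max(t) else span
  tibble::tibble(
    subject_id = as.character(subject_id),
    t = as.numeric(t),
    posture = as.character(posture),
    span = as.numeric(span)
  )
}

#' Read one focal event log
#'
#' Parses a two-column delimited event log (time, posture code), the
#' minimal dialect that event loggers such as JWatcher can export to.
#' Comma- or tab-delimited files are auto-detected; a header line is
#' optional. Times are rebased so the first event sits at its offset from
#' the window start (a non-zero first time is preserved, times are only
#' shifted when `rebase = TRUE`).
#'
#' @param path Path to the log file.
#' @param repertoire Repertoire to validate posture codes against.
#' @param subject_id Id for the sequence; defaults to the file name
#'   without extension.
#' @param time_unit `"s"` (default) or `"ms"`.
#' @param window_length Observation window in seconds.
#' @param span Recorded observation span in seconds (defaults to the last
#'   event time after unit conversion and rebasing).
#' @param rebase Shift times so the earliest event is at 0? Default `TRUE`.
#' @return A sequence tibble as from [behavior_sequence()].
#' @export
read_focal_log <- function(path, repertoire = default_repertoire(),
                           subject_id = NULL, time_unit = c("s", "ms"),
                           window_length = 300, span = NULL,
                           rebase = TRUE) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) {
    abort(paste0("Focal log not found: ", path))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(paste0("Focal log is empty: ", path))
  }
  delim <- if (grepl("\t", lines[[1]])) "\t" else ","
  first_fields <- strsplit(lines[[1]], delim, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(is.na(as.numeric(first_fields[[1]])))
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_names = if (has_header) TRUE else c("t", "posture"),
    col_types = readr::cols(
      readr::col_double(), readr::col_character(),
      .default = readr::col_skip()
    ),
    skip = 0, trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
  names(raw)[1:2] <- c("t", "posture")
  if (anyNA(raw$t)) {
    abort(paste0("Non-numeric time value in ", path, " (line ",
                 which(is.na(raw$t))[1] + has_header, ")."))
  }
  bad <- !(raw$posture %in% repertoire$label)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(paste0(
      "Unknown posture code '", raw$posture[i], "' in ", path,
      " (line ", i + has_header, ")."
    ))
  }
  if (is.unsorted(raw$t, strictly = TRUE)) {
    abort(paste0("Event times in ", path, " are not strictly increasing."))
  }
  t <- raw$t
  if (time_unit == "ms") t <- t / 1000
  if (rebase) t <- t - t[1]
  behavior_sequence(
    subject_id, t, raw$posture,
    repertoire = repertoire, window_length = window_length, span = span
  )
}

#' Write a focal event log
#'
#' Inverse of [read_focal_log()]: writes the two-column (time, posture)
#' dialect. `read_focal_log(write_focal_log(x))` round-trips valid
#' sequences.
#'
#' @param events A sequence tibble for a single subject.
#' @param path Output path.
#' @param delim `","` (default) or `"\t"`.
#' @param header Write a header line? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_focal_log <- function(events, path, delim = ",", header = TRUE) {
  stopifnot(all(c("t", "posture") %in% names(events)))
  if (length(unique(events$subject_id)) > 1) {
    abort("`write_focal_log()` writes one subject per file.")
  }
  readr::write_delim(
    events[, c("t", "posture")], path,
    delim = delim, col_names = header, progress = FALSE
  )
  invisible(path)
}

#' Read a directory of focal logs into one event table
#'
#' @param paths Character vector of log file paths.
#' @param ... Passed on to [read_focal_log()].
#' @return A long tibble of events, one block per file.
#' @export
read_focal_logs <- function(paths, ...) {
  purrr::map(paths, read_focal_log, ...) |>
    purrr::list_rbind()
}

#' Keep only complete fixed-window sequences
#'
#' Focal samples interrupted before the full window (the bird stopped
#' displaying, moved off, or was displaced) are discarded rather than
#' rescaled; retained sequences have their events truncated to the
#' half-open window `[0, window_length)`.
#'
#' @param events Long event tibble with columns `subject_id`, `t`,
#'   `posture` and `span`.
#' @param window_length Required observation span in seconds (default 300).
#' @return The subset of `events` from subjects whose `span` is at least
#'   `window_length`, truncated to the window. May be empty.
#' @examples
#' ev <- behavior_sequence("a", c(0, 5), c("HF", "WS"), span = 300)
#' nrow(filter_complete(ev)) # kept
#' @export
filter_complete <- function(events, window_length = 300) {
  stopifnot(all(c("subject_id", "t", "span") %in% names(events)))
  events |>
    dplyr::filter(.data$span >= window_length, .data$t < window_length)
}
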