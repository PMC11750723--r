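# CSV/JSON interchange: traces are wide CSV (cell_id + one column per frame),
# photometry is long CSV (time_s, sig470, iso405), schedules are JSON

#' Read and write stimulation schedules
#'
#' A schedule JSON stores the acquisition rate, onset times and epoch
#' duration, e.g. `{"fps": 1, "onsets": [30, 62], "epoch_duration": 2}` for
#' imaging or `{"fs": 130, "onsets": [...], "stim_duration": 5}` for
#' photometry.
#'
#' @param path File path.
#' @return `read_schedule()` returns a named list.
#' @export
read_schedule <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_schedule
#' @param schedule Named list to serialise.
#' @export
write_schedule <- function(schedule, path) {
  jsonlite::write_json(schedule, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read per-cell traces from CSV plus a schedule
#'
#' @param file CSV whose first column is `cell_id` and remaining columns are
#'   frames.
#' @param schedule A schedule list (see [read_schedule()]) or a path to a
#'   schedule JSON; must contain `fps`, `onsets`, `epoch_duration`.
#' @return A [trace_matrix()].
#' @export
read_trace_csv <- function(file, schedule) {
  if (is.character(schedule)) schedule <- read_schedule(schedule)
  df <- readr::read_csv(file, show_col_types = FALSE)
  trace_matrix(df, fps = schedule$fps, onsets = schedule$onsets,
               epoch_duration = schedule$epoch_duration)
}

#' @rdname read_trace_csv
#' @param traces A [trace_matrix()].
#' @param path Output CSV path; the schedule is written alongside when
#'   `schedule_path` is given.
#' @param schedule_path Optional path for the schedule JSON.
#' @export
write_trace_csv <- function(traces, path, schedule_path = NULL) {
  stopifnot(inherits(traces, "trace_matrix"))
  df <- as_tibble(traces$values, .name_repair = "minimal")
  names(df) <- sprintf("frame_%d", seq_len(ncol(df)) - 1)
  df <- dplyr::bind_cols(tibble(cell_id = rownames(traces$values)), df)
  readr::write_csv(df, path)
  if (!is.null(schedule_path)) {
    write_schedule(list(fps = traces$fps, onsets = traces$onsets,
                        epoch_duration = traces$epoch_duration),
                   schedule_path)
  }
  invisible(path)
}

#' Read a two-channel photometry recording from CSV plus a schedule
#'
#' @param file CSV with columns `time_s`, `sig470`, `iso405`.
#' @param schedule A schedule list or JSON path with `fs`, `onsets`,
#'   `stim_duration`.
#' @return A [photometry_recording()].
#' @export
read_photometry_csv <- function(file, schedule) {
  if (is.character(schedule)) schedule <- read_schedule(schedule)
  df <- readr::read_csv(file, show_col_types = FALSE)
  photometry_recording(df, fs = schedule$fs, stim_onsets = schedule$onsets,
                       stim_duration = schedule$stim_duration)
}

#' @rdname read_photometry_csv
#' @param rec A [photometry_recording()].
#' @param path Output CSV path.
#' @param schedule_path Optional path for the schedule JSON.
#' @export
write_photometry_csv <- function(rec, path, schedule_path = NULL) {
  stopifnot(inherits(rec, "photometry_recording"))
  readr::write_csv(as_tibble(rec)[c("time_s", "sig470", "iso405")], path)
  if (!is.null(schedule_path)) {
    write_schedule(list(fs = attr(rec, "fs"),
                        onsets = attr(rec, "stim_onsets"),
                        stim_duration = attr(rec, "stim_duration")),
                   schedule_path)
  }
  invisible(path)
}
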