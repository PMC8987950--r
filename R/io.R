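# File I/O: trial recordings as TSV with a JSON event sidecar, cohort and
# metrics tables as CSV. Units are encoded in the column names; headers are
# validated before parsing and malformed rows raise a parse error carrying
# the offending line.

check_header <- function(path, required, delim = "\t") {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort_parse(sprintf("%s: empty file", path))
  got <- strsplit(sub("\r$", "", first), delim, fixed = TRUE)[[1]]
  missing <- setdiff(required, got)
  if (length(missing)) {
    abort_parse(sprintf("%s: header is missing column(s) %s (line 1)",
                        path, paste(missing, collapse = ", ")))
  }
  invisible(got)
}

stop_on_problems <- function(parsed, path) {
  pr <- readr::problems(parsed)
  if (nrow(pr)) {
    abort_parse(sprintf("%s: malformed value at line %d, column %d (%s)",
                        path, pr$row[1], pr$col[1], pr$expected[1]))
  }
  parsed
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read a trial recording (TSV + JSON sidecar)
#'
#' The time series goes to a tab-separated file with columns `t_s`,
#' `lumbar_deg`, `hand_x_m`, `hand_z_m`; event markers and labels (cue,
#' launch and contact times, intercept, game, height, hand, sampling rate)
#' go to a JSON sidecar next to it. Reading restores a `reachvr_trial`
#' identical field-for-field to the one written. CRLF and LF files parse
#' identically.
#'
#' @param rec A `reachvr_trial` recording.
#' @param path TSV file path; the sidecar replaces the extension with
#'   `.json`.
#' @return `write_trial_tsv()` returns `path` invisibly; `read_trial_tsv()`
#'   returns the recording.
#' @export
write_trial_tsv <- function(rec, path) {
  cols <- c("t_s", "lumbar_deg", "hand_x_m", "hand_z_m")
  readr::write_tsv(tibble::as_tibble(rec)[cols], path)
  ev <- trial_events(rec)
  jsonlite::write_json(ev, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_trial_tsv
#' @export
read_trial_tsv <- function(path) {
  cols <- c("t_s", "lumbar_deg", "hand_x_m", "hand_z_m")
  check_header(path, cols)
  tab <- stop_on_problems(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE), path)
  ev <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    ev <- jsonlite::read_json(sc, simplifyVector = TRUE)
    for (f in c("cue_time", "launch_time", "contact_time", "theta_deg",
                "theta_required", "rate")) {
      if (is.null(ev[[f]])) ev[[f]] <- NA_real_
    }
    for (f in c("intercept", "intended")) {
      if (!is.null(ev[[f]])) ev[[f]] <- unlist(ev[[f]])
    }
  }
  structure(tab[cols], class = c("reachvr_trial", class(tab)), events = ev)
}

#' Write / read the participant x game x height cohort table (CSV)
#'
#' @param table Cohort table from [aggregate_trials()].
#' @param path CSV file path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns a tibble.
#' @export
write_cohort_csv <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  check_header(path, c("participant", "game", "theta_deg"), delim = ",")
  stop_on_problems(readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
                   path)
}

#' Write per-trial metrics as CSV
#'
#' @param metrics Per-trial metrics from [trial_metrics()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  readr::write_csv(tibble::as_tibble(metrics), path)
  invisible(path)
}
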