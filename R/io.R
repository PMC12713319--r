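# TSV dialects for one session: samples.tsv (t_ms, pupil, gaze_x, gaze_y),
# events.tsv (kind, start_ms, end_ms), trials.tsv (trial table schema).
# Missing pupil is encoded as an empty cell or 0 (device sentinel); it becomes
# valid = FALSE on read and is written back as 0.

#' Read a pupil sample file
#'
#' Two dialects are supported. `"tsv-samples"` is the native format: a
#' commented header line `# rate_hz: <rate>` followed by a TSV with columns
#' `t_ms`, `pupil` and optionally `gaze_x`, `gaze_y`; blank or zero pupil
#' cells are missing-data sentinels. `"asc-like"` is a thin adapter for
#' EyeLink-style ASC exports: whitespace-delimited sample lines
#' `<t_ms> <x> <y> <pupil>` (dots or zeros for missing), all other lines
#' ignored except `EBLINK`/`ESACC` which are collected by [read_events_asc()].
#'
#' @param path file path.
#' @param dialect `"tsv-samples"` or `"asc-like"`.
#' @param rate sampling rate in Hz; required for `"asc-like"` (the native
#'   dialect declares it in its header).
#' @return A [pupil_recording()].
#' @export
read_samples <- function(path, dialect = c("tsv-samples", "asc-like"), rate = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dialect <- match.arg(dialect)
  if (dialect == "tsv-samples") {
    header <- readLines(path, n = 1L)
    m <- regmatches(header, regexec("^#\\s*rate_hz:\\s*([0-9.]+)", header))[[1]]
    if (length(m) < 2) stop("samples file must start with '# rate_hz: <rate>'")
    rate <- as.numeric(m[2])
    df <- utils::read.delim(path, comment.char = "#", na.strings = c("", "NA"))
    pupil <- df$pupil
    valid <- !is.na(pupil) & pupil != 0
    pupil[!valid] <- 0
    t <- df$t_ms / 1000
    if (any(diff(t) <= 0)) stop("non-monotone time")
    pupil_recording(t, pupil, rate = rate, valid = valid,
                    gaze_x = df$gaze_x, gaze_y = df$gaze_y)
  } else {
    if (is.null(rate)) stop("asc-like dialect requires an explicit rate")
    lines <- readLines(path)
    samp <- grep("^[0-9]", lines, value = TRUE)
    fields <- strsplit(trimws(samp), "\\s+")
    t_ms <- vapply(fields, function(f) as.numeric(f[1]), 0)
    pup <- vapply(fields, function(f) {
      v <- suppressWarnings(as.numeric(f[4]))
      if (is.na(v)) 0 else v
    }, 0)
    if (any(diff(t_ms) <= 0)) stop("non-monotone time")
    pupil_recording((t_ms - t_ms[1]) / 1000, pup, rate = rate,
                    valid = pup != 0)
  }
}

#' @rdname read_samples
#' @param rec a `cb_recording`.
#' @export
write_samples <- function(rec, path) {
  pupil <- rec$pupil
  pupil[!rec$valid] <- 0
  df <- data.frame(t_ms = round(rec$t * 1000), pupil = pupil)
  if (!is.null(rec$gaze_x)) df$gaze_x <- rec$gaze_x
  if (!is.null(rec$gaze_y)) df$gaze_y <- rec$gaze_y
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz: %g", rec$rate), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write blink and saccade events
#'
#' `events.tsv` has columns `kind`, `start_ms`, `end_ms` with the half-open
#' `[start, end)` convention. Overlapping same-kind rows are merged on read
#' (with a warning); an empty file yields an empty table.
#'
#' @param path file path.
#' @return A [event_table()].
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path)
  event_table(df$kind, df$start_ms, df$end_ms)
}

#' @rdname read_events
#' @param events a `cb_events` table.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract blink/saccade events from an asc-like export
#'
#' Parses `EBLINK <eye> <start> <end>` and `ESACC <eye> <start> <end> ...`
#' lines; all other content is ignored.
#'
#' @param path file path.
#' @param t0_ms tracker timestamp of the first sample (subtracted so events
#'   share the recording's time origin).
#' @return A [event_table()].
#' @export
read_events_asc <- function(path, t0_ms = 0) {
  lines <- readLines(path)
  parse_kind <- function(tag, kind) {
    rows <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (!length(rows)) return(NULL)
    f <- strsplit(trimws(rows), "\\s+")
    data.frame(kind = kind,
               start_ms = vapply(f, function(x) as.numeric(x[3]), 0) - t0_ms,
               end_ms = vapply(f, function(x) as.numeric(x[4]), 0) - t0_ms)
  }
  df <- rbind(parse_kind("EBLINK", "blink"), parse_kind("ESACC", "saccade"))
  if (is.null(df)) return(event_table())
  event_table(df$kind, df$start_ms, df$end_ms)
}

#' Read / write a trial log
#'
#' `trials.tsv` carries the full trial-table schema; the table is validated
#' against the configuration (condition counts, rating ranges, onset order)
#' on read.
#'
#' @param path file path.
#' @param config a `cb_config`.
#' @return A [trial_table()].
#' @export
read_trial_log <- function(path, config) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, na.strings = c("", "NA"))
  df$retrospective_flag <- as.logical(df$retrospective_flag)
  df$retro_false_positive_flag <- as.logical(df$retro_false_positive_flag)
  trial_table(df, config)
}

#' @rdname read_trial_log
#' @param trials a `cb_trials` table.
#' @export
write_trial_log <- function(trials, path) {
  utils::write.table(as.data.frame(trials), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generated cohort to a directory
#'
#' Writes per-subject `samples.tsv`, `events.tsv`, `trials.tsv` under
#' `<dir>/<subject>/`, plus `ground_truth.tsv` and `config.yaml` at the top
#' level.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$subjects)) {
    sd <- file.path(dir, id)
    dir.create(sd, showWarnings = FALSE)
    s <- cohort$subjects[[id]]
    write_samples(s$recording, file.path(sd, "samples.tsv"))
    write_events(s$events, file.path(sd, "events.tsv"))
    write_trial_log(s$trials, file.path(sd, "trials.tsv"))
  }
  utils::write.table(cohort$ground_truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return A list with `subjects` (each `recording`, `events`, `trials`),
#'   `ground_truth`, `config`.
#' @export
read_cohort <- function(dir) {
  config <- read_config(file.path(dir, "config.yaml"))
  ids <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  subjects <- lapply(ids, function(id) {
    sd <- file.path(dir, id)
    list(recording = read_samples(file.path(sd, "samples.tsv")),
         events = read_events(file.path(sd, "events.tsv")),
         trials = read_trial_log(file.path(sd, "trials.tsv"), config))
  })
  names(subjects) <- ids
  gt <- utils::read.delim(file.path(dir, "ground_truth.tsv"))
  list(subjects = subjects, ground_truth = gt, config = config)
}
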