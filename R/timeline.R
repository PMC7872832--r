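# Ingest of step-count tables and alignment onto the perioperative grid.
#
# Timestamps are treated as naive local wall-clock time and parsed in a fixed
# UTC frame, so a calendar day is always midnight-to-midnight and an hour bin
# is always the clock-hour label (00:00-00:59 -> bin 0).

#' Column mapping for a step-count table
#'
#' Describes how to read a delimited step table: which columns hold the
#' patient id, timestamp and step count, the timestamp formats to try, and
#' whether rows are per-minute or per-hour.
#'
#' @param patient_col,time_col,steps_col Column names in the input table.
#' @param resolution `"minute"` (default) or `"hour"`. Affects only the
#'   `minutes_observed` provenance counter; binning is identical.
#' @param time_formats Candidate `strptime` formats tried in order.
#' @return A `pw_dialect` list.
#' @export
steps_dialect <- function(patient_col = "patient_id",
                          time_col = "timestamp",
                          steps_col = "steps",
                          resolution = c("minute", "hour"),
                          time_formats = c("%Y-%m-%d %H:%M:%S",
                                           "%Y-%m-%d %H:%M",
                                           "%Y-%m-%dT%H:%M:%S",
                                           "%Y-%m-%dT%H:%M")) {
  resolution <- match.arg(resolution)
  structure(list(patient_col = patient_col, time_col = time_col,
                 steps_col = steps_col, resolution = resolution,
                 time_formats = time_formats),
            class = "pw_dialect")
}

parse_timestamps <- function(x, formats) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  todo <- rep(TRUE, length(x))
  for (fmt in formats) {
    if (!any(todo)) break
    parsed <- as.POSIXct(x[todo], format = fmt, tz = "UTC")
    hit <- !is.na(parsed)
    out[which(todo)[hit]] <- parsed[hit]
    todo[todo] <- !hit
  }
  out
}

#' Read a step-count table
#'
#' Reads a delimited text table of per-minute (or per-hour) step counts into
#' a canonical record table with one row per observation. Rows with negative
#' step counts or unparseable timestamps are dropped and reported via the
#' `"issues"` attribute.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed by
#'   [data.table::fread()]).
#' @param dialect A [steps_dialect()] describing the columns.
#' @return A `data.table` with columns `patient_id` (character), `timestamp`
#'   (POSIXct) and `steps` (integer), keyed by patient. Attribute `issues`
#'   is a list with counts of rejected rows.
#' @export
read_steps_table <- function(path, dialect = steps_dialect()) {
  stopifnot(inherits(dialect, "pw_dialect"))
  hdr <- names(data.table::fread(path, nrows = 0L))
  need <- c(dialect$patient_col, dialect$time_col, dialect$steps_col)
  missing_cols <- setdiff(need, hdr)
  if (!length(missing_cols)) {
    dt <- data.table::fread(path,
                            colClasses = list(character = dialect$time_col))
  } else {
    stop("step table ", path, " lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(dt) == 0L) {
    warning("step table ", path, " has no data rows", call. = FALSE)
    empty <- data.table::data.table(patient_id = character(),
                                    timestamp = as.POSIXct(character(), tz = "UTC"),
                                    steps = integer())
    data.table::setattr(empty, "issues",
                        list(n_negative = 0L, n_bad_timestamp = 0L))
    return(empty)
  }
  rec <- data.table::data.table(
    patient_id = as.character(dt[[dialect$patient_col]]),
    timestamp  = parse_timestamps(as.character(dt[[dialect$time_col]]),
                                  dialect$time_formats),
    steps      = suppressWarnings(as.numeric(dt[[dialect$steps_col]]))
  )
  bad_ts <- is.na(rec$timestamp)
  neg <- !bad_ts & (is.na(rec$steps) | rec$steps < 0)
  if (any(bad_ts)) {
    warning(sum(bad_ts), " row(s) with unparseable timestamps skipped",
            call. = FALSE)
  }
  if (any(neg)) {
    warning(sum(neg), " row(s) with negative or non-numeric step counts rejected",
            call. = FALSE)
  }
  rec <- rec[!bad_ts & !neg]
  rec[, steps := as.integer(round(steps))]
  data.table::setkeyv(rec, "patient_id")
  data.table::setattr(rec, "issues",
                      list(n_negative = sum(neg), n_bad_timestamp = sum(bad_ts)))
  rec[]
}

#' Read patient metadata
#'
#' @param path CSV with columns `patient_id`, `surgery_date` (ISO date),
#'   `age`, `gender`, `bmi`, `asa`, `device` (`clip` or `wrist`).
#' @return A data.frame, one validated row per patient.
#' @export
read_patient_meta <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "patient_id"))
  need <- c("patient_id", "surgery_date", "age", "gender", "bmi", "asa", "device")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("metadata table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  meta <- as.data.frame(dt)
  meta$patient_id <- as.character(meta$patient_id)
  meta$surgery_date <- as.Date(meta$surgery_date)
  validate_meta(meta)
  meta
}

validate_meta <- function(meta) {
  if (anyDuplicated(meta$patient_id)) {
    stop("duplicate patient_id in metadata", call. = FALSE)
  }
  if (any(is.na(meta$surgery_date))) stop("unparseable surgery_date", call. = FALSE)
  if (!all(meta$device %in% c("clip", "wrist"))) {
    stop("device must be 'clip' or 'wrist'", call. = FALSE)
  }
  if (!all(meta$age > 0)) stop("age must be positive", call. = FALSE)
  if (!all(meta$bmi > 0)) stop("bmi must be positive", call. = FALSE)
  if (!all(meta$asa %in% 1:5)) stop("asa must be an integer class 1-5", call. = FALSE)
  invisible(meta)
}

new_timeline <- function(meta, hourly, minutes_observed, n_dropped = 0L) {
  stopifnot(nrow(hourly) == 57L, ncol(hourly) == 24L, all(hourly >= 0))
  storage.mode(hourly) <- "integer"
  dimnames(hourly) <- list(as.character(day_indices()), as.character(0:23))
  structure(list(meta = meta, hourly = hourly,
                 minutes_observed = stats::setNames(as.integer(minutes_observed),
                                                    as.character(day_indices())),
                 n_dropped = as.integer(n_dropped)),
            class = "pw_timeline")
}

#' Build a patient timeline from step records
#'
#' Aligns one patient's records onto the 57-day perioperative grid. The day
#' index of a record is the whole-day difference between its calendar date
#' and the surgery date; records outside \[-14, 42\] are dropped (the count
#' is kept in `n_dropped`). Step counts are summed into 24 clock-hour bins.
#' Days with no records become all-zero days with `minutes_observed = 0`,
#' because an absent day is a non-wear day, not missing data, for every
#' compliance criterion.
#'
#' @param records Record table (as from [read_steps_table()]) for a single
#'   patient; extra patients' rows are an error.
#' @param meta A single-row data.frame of patient metadata including
#'   `surgery_date`.
#' @return A `pw_timeline`: list with `meta`, a 57x24 integer `hourly`
#'   matrix (rows = day index -14..42, columns = hour 0..23),
#'   `minutes_observed` per day, and `n_dropped`.
#' @export
build_timeline <- function(records, meta) {
  stopifnot(is.data.frame(meta), nrow(meta) == 1L)
  if (is.na(meta$surgery_date)) stop("surgery_date must be set", call. = FALSE)
  hourly <- matrix(0L, 57L, 24L)
  minutes <- integer(57L)
  n_drop <- 0L
  if (nrow(records)) {
    if (length(unique(records$patient_id)) > 1L) {
      stop("build_timeline expects records for a single patient", call. = FALSE)
    }
    date <- as.Date(format(records$timestamp, "%Y-%m-%d", tz = "UTC"))
    day_index <- as.integer(date - as.Date(meta$surgery_date))
    hour <- as.integer(format(records$timestamp, "%H", tz = "UTC"))
    keep <- day_index >= DAY_MIN & day_index <= DAY_MAX
    n_drop <- sum(!keep)
    if (any(keep)) {
      row <- day_index[keep] - DAY_MIN + 1L
      col <- hour[keep] + 1L
      cell <- (col - 1L) * 57L + row
      acc <- rowsum(records$steps[keep], cell)
      hourly[as.integer(rownames(acc))] <- as.integer(acc)
      mo <- rowsum(rep(1L, sum(keep)), row)
      minutes[as.integer(rownames(mo))] <- as.integer(mo)
    }
  }
  new_timeline(meta, hourly, minutes, n_drop)
}

#' @export
print.pw_timeline <- function(x, ...) {
  cat("<pw_timeline> patient", x$meta$patient_id,
      "| surgery", format(x$meta$surgery_date),
      "| device", x$meta$device, "\n")
  cat("  57 days x 24 hours;", sum(x$hourly), "steps;",
      sum(rowSums(x$hourly) > 0), "days with data;",
      x$n_dropped, "out-of-window record(s) dropped\n")
  invisible(x)
}

#' Build a cohort of aligned timelines
#'
#' @param records Record table covering any number of patients.
#' @param meta Metadata data.frame with one row per patient (every patient
#'   in `meta` gets a timeline; patients with no records get an all-zero
#'   one).
#' @return A `pw_cohort`: list of `timelines` (named by patient) and the
#'   `meta` table.
#' @export
build_cohort <- function(records, meta) {
  validate_meta(meta)
  extra <- setdiff(unique(records$patient_id), meta$patient_id)
  if (length(extra)) {
    warning("records for patient(s) absent from metadata ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  timelines <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, , drop = FALSE]
    build_timeline(records[records$patient_id == m$patient_id, , drop = FALSE], m)
  })
  names(timelines) <- meta$patient_id
  structure(list(timelines = timelines, meta = meta), class = "pw_cohort")
}

#' @export
print.pw_cohort <- function(x, ...) {
  cat("<pw_cohort>", length(x$timelines), "patients x 57 days\n")
  cat("  devices:", paste(names(table(x$meta$device)), table(x$meta$device),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Tidy long view of a cohort
#'
#' @param cohort A `pw_cohort`.
#' @return data.table with columns `patient_id`, `day_index`, `hour`,
#'   `steps` (57 x 24 rows per patient), the canonical interchange table
#'   written by the CLI.
#' @export
cohort_long <- function(cohort) {
  stopifnot(inherits(cohort, "pw_cohort"))
  data.table::rbindlist(lapply(cohort$timelines, function(tl) {
    data.table::data.table(
      patient_id = tl$meta$patient_id,
      day_index = rep(day_indices(), times = 24L),
      hour = rep(0:23, each = 57L),
      steps = as.integer(tl$hourly)
    )
  }))[order(patient_id, day_index, hour)]
}

#' Day indices of a perioperative stage
#'
#' The four two-week stages partition the window minus the surgery day:
#' `presurgery` = -14..-1, `weeks_0_2` = 1..14, `weeks_2_4` = 15..28,
#' `weeks_4_6` = 29..42. Day 0 belongs to no stage.
#'
#' @param name Stage name.
#' @return Integer vector of 14 day indices.
#' @export
#' @examples
#' stage_days("presurgery")
stage_days <- function(name) {
  switch(match.arg(name, STAGE_NAMES),
         presurgery = -14:-1,
         weeks_0_2  = 1:14,
         weeks_2_4  = 15:28,
         weeks_4_6  = 29:42)
}

#' Stage names in chronological order
#' @return Character vector of the four stage names.
#' @export
stage_names <- function() STAGE_NAMES
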