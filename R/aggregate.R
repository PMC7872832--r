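# Summaries of the compliance matrix: per-patient period compliance,
# two-week stage compliance, daily sample rates, across-criteria
# mean/SD deviation series, baseline differences, and data retention.

check_matrix <- function(matrix) {
  stopifnot(is.data.frame(matrix),
            all(c("patient_id", "day_index", "criterion", "valid") %in%
                  names(matrix)))
  invisible(matrix)
}

#' Per-patient period compliance
#'
#' Fraction of valid days over a day window, per patient and criterion. The
#' denominator is the full window size: days without data are already
#' scored invalid, never excluded.
#'
#' @param matrix A compliance matrix from [evaluate_matrix()].
#' @param day_range Integer day indices, a nonempty subset of -14..42.
#'   Defaults to the whole 57-day perioperative period (surgery day
#'   included).
#' @return data.table `patient_id`, `criterion`, `value` with
#'   `value` in \[0, 1\].
#' @export
period_compliance <- function(matrix, day_range = day_indices()) {
  check_matrix(matrix)
  if (length(day_range) == 0L) stop("day_range must be nonempty", call. = FALSE)
  if (!all(day_range %in% day_indices())) {
    stop("day_range must lie within -14..42", call. = FALSE)
  }
  day_range <- unique(as.integer(day_range))
  dt <- data.table::as.data.table(matrix)[day_index %in% day_range]
  out <- dt[, .(value = sum(valid) / length(day_range)),
            by = .(patient_id, criterion)]
  out[order(patient_id, criterion)]
}

#' Two-week stage compliance
#'
#' Period compliance within each of the four two-week stages; the surgery
#' day (index 0) contributes to no stage, so every denominator is 14.
#'
#' @inheritParams period_compliance
#' @return data.table `patient_id`, `stage`, `criterion`, `value`.
#' @export
stage_compliance <- function(matrix) {
  check_matrix(matrix)
  out <- data.table::rbindlist(lapply(stage_names(), function(s) {
    pc <- period_compliance(matrix, stage_days(s))
    pc[, stage := s]
    pc
  }))
  data.table::setcolorder(out, c("patient_id", "stage", "criterion", "value"))
  out[order(patient_id, stage, criterion)]
}

#' Daily sample compliance rate
#'
#' Fraction of the cohort valid on each day under each criterion (the
#' quantity behind the daily compliance line plots).
#'
#' @inheritParams period_compliance
#' @return data.table `day_index`, `criterion`, `rate`.
#' @export
daily_sample_rate <- function(matrix) {
  check_matrix(matrix)
  dt <- data.table::as.data.table(matrix)
  if (nrow(dt) == 0L) stop("empty compliance matrix", call. = FALSE)
  out <- dt[, .(rate = mean(valid)), by = .(day_index, criterion)]
  out[order(day_index, criterion)]
}

#' Mean and deviation across criteria
#'
#' Arithmetic mean and standard deviation of a set of per-criterion
#' compliance values (canonically the five criterion rates for one day, or
#' one patient's five period outcomes).
#'
#' @param rates Numeric vector of per-criterion values (length >= 2;
#'   canonically 5).
#' @param sd_denominator `"sample"` (n-1, default) or `"population"` (n).
#' @return Named numeric vector `c(mean = , sd = )`.
#' @export
across_criteria_stats <- function(rates, sd_denominator = c("sample", "population")) {
  sd_denominator <- match.arg(sd_denominator)
  stopifnot(is.numeric(rates), length(rates) >= 2L, !anyNA(rates))
  n <- length(rates)
  s <- stats::sd(rates)
  if (sd_denominator == "population") s <- s * sqrt((n - 1) / n)
  c(mean = mean(rates), sd = s)
}

#' Daily across-criteria deviation series
#'
#' For each day: the per-criterion sample rates, their mean, and the
#' standard deviation between them — the series behind the mean +/- SD
#' band plots.
#'
#' @inheritParams across_criteria_stats
#' @inheritParams period_compliance
#' @return data.table `day_index`, `mean`, `sd`; per-criterion rates are
#'   available from [daily_sample_rate()].
#' @export
deviation_series <- function(matrix, sd_denominator = c("sample", "population")) {
  sd_denominator <- match.arg(sd_denominator)
  rates <- daily_sample_rate(matrix)
  out <- rates[, {
    st <- across_criteria_stats(rate, sd_denominator)
    .(mean = st[["mean"]], sd = st[["sd"]])
  }, by = day_index]
  out[order(day_index)]
}

#' Baseline differences against the most lenient criterion
#'
#' Per patient, the drop in period compliance from the `gt0_steps` baseline
#' to each other criterion. By the dominance property these differences are
#' always non-negative. Patients are ranked by their total deviation.
#'
#' @param period A table from [period_compliance()] including `gt0_steps`.
#' @return data.table `patient_id`, `criterion`, `baseline`, `value`,
#'   `difference`, plus `total_deviation` (per patient, sum of
#'   differences), ordered by increasing total deviation.
#' @export
baseline_differences <- function(period) {
  stopifnot(all(c("patient_id", "criterion", "value") %in% names(period)))
  dt <- data.table::as.data.table(period)
  base <- dt[criterion == "gt0_steps", .(patient_id, baseline = value)]
  if (nrow(base) == 0L) {
    stop("baseline criterion 'gt0_steps' missing from period table",
         call. = FALSE)
  }
  out <- merge(dt[criterion != "gt0_steps"], base, by = "patient_id")
  out[, difference := baseline - value]
  out[, total_deviation := sum(difference), by = patient_id]
  data.table::setcolorder(out, c("patient_id", "criterion", "baseline",
                                 "value", "difference", "total_deviation"))
  out[order(total_deviation, patient_id, criterion)]
}

#' Data retention per criterion
#'
#' How many patient-days each criterion keeps versus discards — the
#' practical consequence of criterion choice.
#'
#' @inheritParams period_compliance
#' @return data.table `criterion`, `retained`, `discarded`, `total`,
#'   `retained_frac`.
#' @export
retention_report <- function(matrix) {
  check_matrix(matrix)
  dt <- data.table::as.data.table(matrix)
  out <- dt[, .(retained = sum(valid), discarded = sum(!valid),
                total = .N), by = criterion]
  out[, retained_frac := retained / total]
  out[order(criterion)]
}

#' Per-patient between-criteria deviation features
#'
#' One row per patient: the standard deviation of the five whole-period
#' compliance outcomes (the sensitivity of that patient's reported
#' compliance to criterion choice), joined to metadata with the 0/1 codings
#' used by the association analyses (clip = 0, wrist = 1).
#'
#' @param period Table from [period_compliance()].
#' @param meta Patient metadata data.frame.
#' @inheritParams across_criteria_stats
#' @return data.table `patient_id`, `sd_compliance`, `mean_compliance`,
#'   `device`, `device01`, `age`, `gender`, `gender01`, `bmi`, `asa`.
#' @export
patient_features <- function(period, meta,
                             sd_denominator = c("sample", "population")) {
  sd_denominator <- match.arg(sd_denominator)
  dt <- data.table::as.data.table(period)
  feats <- dt[, {
    st <- across_criteria_stats(value, sd_denominator)
    .(mean_compliance = st[["mean"]], sd_compliance = st[["sd"]])
  }, by = patient_id]
  m <- data.table::as.data.table(meta)[, .(patient_id, device, age, gender, bmi, asa)]
  out <- merge(feats, m, by = "patient_id")
  out[, device01 := as.integer(device == "wrist")]
  out[, gender01 := as.integer(gender %in% c("F", "f", "female", "Female"))]
  out[order(patient_id)]
}
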