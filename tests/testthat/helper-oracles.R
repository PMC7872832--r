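# Minute-level brute-force oracles, independent of the package's
# hour-vector predicates: each one scans raw minute counts (minute of day
# 0..1439) directly. Used to cross-validate every criterion on random days.

minutes_to_hourly <- function(mins) {
  stopifnot(length(mins) == 1440L)
  as.vector(rowsum(mins, rep(0:23, each = 60L)))
}

o_gt0 <- function(mins) sum(mins) >= 1

o_gt500 <- function(mins) sum(mins) > 500

o_ge10_hours <- function(mins) {
  hours <- rep(0:23, each = 60L)
  length(unique(hours[mins > 0])) >= 10L
}

# windows in minutes of day: 3am-11am = [180, 660), 11am-3pm = [660, 900),
# 3pm-3am = [900, 1440) plus [0, 180) of the next day when wrapping
o_three_a_day <- function(mins, next_mins = NULL, wrap = TRUE) {
  w1 <- sum(mins[181:660])
  w2 <- sum(mins[661:900])
  w3 <- sum(mins[901:1440])
  if (wrap && !is.null(next_mins)) w3 <- w3 + sum(next_mins[1:180])
  w1 >= 1 && w2 >= 1 && w3 >= 1
}

o_three_of_four <- function(mins) {
  wins <- c(sum(mins[1:360]), sum(mins[361:720]),
            sum(mins[721:1080]), sum(mins[1081:1440]))
  sum(wins >= 1) >= 3L
}

# sparse random minute day: a handful of active minutes with small counts,
# occasionally empty or dense
random_minutes <- function() {
  mins <- integer(1440L)
  n_active <- sample(c(0L, 1L, 2L, 3L, 5L, 10L, 25L, 80L, 300L), 1L,
                     prob = c(.1, .15, .1, .1, .15, .15, .1, .1, .05))
  if (n_active > 0L) {
    pos <- sample.int(1440L, n_active)
    mins[pos] <- sample(c(1L, 2L, 5L, 30L, 200L), n_active, replace = TRUE)
  }
  mins
}

# hourly day with steps concentrated in the given clock hours
make_hourly <- function(...) {
  pairs <- list(...)
  h <- integer(24L)
  for (p in pairs) h[p[1] + 1L] <- p[2]
  h
}

# tiny deterministic record table for ingest tests
write_steps_csv <- function(path, rows) {
  writeLines(c("patient_id,timestamp,steps", rows), path)
  path
}

small_meta <- function(ids = "P01", surgery = "2017-06-01",
                       device = "wrist") {
  data.frame(patient_id = ids, surgery_date = as.Date(surgery),
             age = 65, gender = "F", bmi = 30, asa = 2L,
             device = device, stringsAsFactors = FALSE)
}

# cohort built directly from hourly matrices (bypasses ingest)
cohort_from_hourly <- function(hourly_list, meta) {
  tls <- lapply(seq_along(hourly_list), function(i) {
    m <- meta[i, , drop = FALSE]
    h <- hourly_list[[i]]
    structure(list(meta = m, hourly = matrix(as.integer(h), 57L, 24L,
                                             dimnames = list(as.character(-14:42),
                                                             as.character(0:23))),
                   minutes_observed = stats::setNames(integer(57L),
                                                      as.character(-14:42)),
                   n_dropped = 0L),
              class = "pw_timeline")
  })
  names(tls) <- meta$patient_id
  structure(list(timelines = tls, meta = meta), class = "pw_cohort")
}
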