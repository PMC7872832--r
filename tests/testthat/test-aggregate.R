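# fixture: one patient valid on a known set of days under one criterion
matrix_fixture <- function(valid_days, criterion = "gt0_steps",
                           patient = "P01") {
  data.table::data.table(patient_id = patient,
                         day_index = rep(day_indices(), length(criterion)),
                         criterion = rep(criterion, each = 57L),
                         valid = rep(day_indices() %in% valid_days,
                                     length(criterion)))
}

test_that("period compliance counts valid days over the full window", {
  m <- matrix_fixture(day_indices())
  expect_equal(period_compliance(m)$value, 1.0)
  m16 <- matrix_fixture(c(-14:-10, 1:11))   # 16 valid of 57
  expect_equal(period_compliance(m16)$value, 16 / 57)
  expect_error(period_compliance(m, integer()), "nonempty")
  expect_error(period_compliance(m, 43L), "-14..42")
  # restricted windows use the window size as denominator
  expect_equal(period_compliance(m16, -14:-10)$value, 1.0)
})

test_that("stage compliance excludes day 0 and uses denominator 14", {
  m_all <- matrix_fixture(day_indices())
  st <- stage_compliance(m_all)
  expect_equal(nrow(st), 4L)
  expect_true(all(st$value == 1.0))
  m_wk02 <- stage_compliance(matrix_fixture(1:14))
  expect_equal(m_wk02$value[m_wk02$stage == "weeks_0_2"], 1.0)
  expect_equal(sum(m_wk02$value[m_wk02$stage != "weeks_0_2"]), 0.0)
  m_half <- stage_compliance(matrix_fixture(29:35))
  expect_equal(m_half$value[m_half$stage == "weeks_4_6"], 0.5)
  # day 0 alone contributes to no stage
  m_d0 <- stage_compliance(matrix_fixture(0L))
  expect_true(all(m_d0$value == 0.0))
})

test_that("whole-period compliance decomposes over stages plus day 0", {
  set.seed(11)
  sim <- simulate_cohort(sim_config(n_patients = 6, seed = 11))
  m <- evaluate_matrix(sim$cohort)
  whole <- period_compliance(m)
  st <- stage_compliance(m)
  d0 <- period_compliance(m, 0L)
  agg <- merge(st[, .(stage_days_valid = sum(value) * 14),
                 by = .(patient_id, criterion)],
               d0[, .(patient_id, criterion, d0_valid = value)],
               by = c("patient_id", "criterion"))
  agg <- merge(agg, whole, by = c("patient_id", "criterion"))
  expect_equal(agg$value, (agg$stage_days_valid + agg$d0_valid) / 57)
})

test_that("daily sample rate is the fraction of patients valid that day", {
  m <- data.table::rbindlist(lapply(sprintf("P%02d", 1:20), function(p) {
    matrix_fixture(if (p <= "P10") 5L else integer(), patient = p)
  }))
  r <- daily_sample_rate(m)
  expect_equal(r$rate[r$day_index == 5L], 0.5)
  expect_equal(r$rate[r$day_index == 6L], 0.0)
})

test_that("across-criteria stats use the requested SD denominator", {
  expect_equal(across_criteria_stats(rep(0.8, 5)), c(mean = 0.8, sd = 0))
  st <- across_criteria_stats(c(1, 0, 0, 0, 0))
  expect_equal(st[["mean"]], 0.2)
  expect_equal(st[["sd"]], sqrt(0.2), tolerance = 1e-12)
  stp <- across_criteria_stats(c(1, 0, 0, 0, 0), "population")
  expect_equal(stp[["sd"]], 0.4)
  expect_error(across_criteria_stats(0.5), "length")
})

test_that("deviation series has zero SD iff the five rates agree", {
  m <- data.table::rbindlist(lapply(builtin_criteria(), function(cr) {
    matrix_fixture(1:10, criterion = cr)
  }))
  ds <- deviation_series(m)
  expect_equal(nrow(ds), 57L)
  expect_true(all(ds$sd == 0))
  # make one criterion disagree on day 1
  m$valid[m$criterion == "gt0_steps" & m$day_index == 20L] <- TRUE
  ds2 <- deviation_series(m)
  expect_gt(ds2$sd[ds2$day_index == 20L], 0)
  expect_equal(ds2$mean[ds2$day_index == 20L], 0.2)
})

test_that("baseline differences are gaps from the most lenient criterion", {
  pc <- data.table::data.table(
    patient_id = rep(c("P01", "P20"), each = 5L),
    criterion = rep(builtin_criteria(), 2L),
    value = c(rep(0.9, 5), 1.00, 0.80, 0.28, 0.70, 0.70))
  bd <- baseline_differences(pc)
  expect_equal(nrow(bd), 8L)
  expect_true(all(bd$difference[bd$patient_id == "P01"] == 0))
  expect_equal(bd$difference[bd$patient_id == "P20" &
                               bd$criterion == "ge10_hours"], 0.72)
  # ordered by total deviation: the unaffected patient first
  expect_equal(bd$patient_id[1], "P01")
  expect_error(baseline_differences(pc[criterion != "gt0_steps"]), "gt0_steps")
})

test_that("dominance makes every gt0 summary an upper bound", {
  sim <- simulate_cohort(sim_config(n_patients = 8, seed = 3))
  m <- evaluate_matrix(sim$cohort)
  pc <- period_compliance(m)
  wide <- data.table::dcast(pc, patient_id ~ criterion, value.var = "value")
  for (cr in setdiff(builtin_criteria(), "gt0_steps")) {
    expect_true(all(wide$gt0_steps >= wide[[cr]]))
  }
  bd <- baseline_differences(pc)
  expect_true(all(bd$difference >= -1e-12))
  r <- retention_report(m)
  expect_true(all(r$retained[r$criterion == "gt0_steps"] >= r$retained))
  expect_equal(r$retained + r$discarded, r$total)
  ds <- deviation_series(m)
  rates <- daily_sample_rate(m)
  gt0 <- rates$rate[rates$criterion == "gt0_steps"]  # already in day order
  expect_true(all(ds$mean <= gt0 + 1e-12))
})

test_that("retention report counts retained vs discarded patient-days", {
  sparse <- matrix(0L, 57L, 24L)
  sparse[16, c(4, 12, 20) + 1] <- 1L
  m <- evaluate_matrix(cohort_from_hourly(list(sparse), small_meta()))
  r <- retention_report(m)
  expect_equal(r$retained[r$criterion %in%
                            c("gt0_steps", "three_a_day", "three_of_four")],
               c(1L, 1L, 1L))
  expect_equal(r$retained[r$criterion %in% c("gt500_steps", "ge10_hours")],
               c(0L, 0L))
  expect_equal(unique(r$total), 57L)
  m_all <- matrix_fixture(day_indices())
  r_all <- retention_report(m_all)
  expect_equal(r_all$discarded, 0L)
})

test_that("patient features carry the across-criteria SD and codings", {
  pc <- data.table::data.table(patient_id = rep("P01", 5L),
                               criterion = builtin_criteria(),
                               value = c(1, 0, 0, 0, 0))
  feats <- patient_features(pc, small_meta())
  expect_equal(feats$sd_compliance, sqrt(0.2), tolerance = 1e-12)
  expect_equal(feats$device01, 1L)   # wrist = 1
  expect_equal(feats$gender01, 1L)   # F = 1
})
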