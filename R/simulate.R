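# Synthetic perioperative cohort generator.
#
# One patient-day is simulated in three layers:
#   worn?      Bernoulli on a day-specific wear probability (clip devices
#              carry an extra daily forget probability),
#   when?      a waking-hours wear window drawn around configurable start
#              and end times (clip devices lose evening hours in the first
#              post-operative weeks),
#   how much?  zero-inflated negative-binomial hourly counts whose mean
#              follows a diurnal template scaled by the patient's activity
#              level and by the surgery dip-and-recovery multiplier.
# Step data are bursty: the hour-level zero inflation models activity
# bouts, so low-intensity days concentrate steps into few clock hours,
# which is exactly what separates the hour- and window-based criteria from
# the plain step-count ones after surgery.

#' Simulator configuration
#'
#' Defaults describe a cohort like the motivating one: 20 total-knee
#' arthroplasty patients, ~60% wrist-worn devices, high presurgery wear,
#' a transient wear drop and a deep activity dip after surgery with
#' recovery over about five weeks, and clip-specific evening wear loss in
#' the first two postoperative weeks.
#'
#' @param n_patients Cohort size.
#' @param seed RNG seed (the whole cohort is reproducible from it).
#' @param wear_prob_pre Mean probability a presurgery day is worn.
#' @param wear_prob_post_curve Numeric vector of 43 wear probabilities for
#'   days 0..42, or `NULL` for the default curve (brief day-0 bump, dip to
#'   `wear_prob_post_min`, linear return to `wear_prob_pre` by day
#'   `wear_recovery_days`).
#' @param wear_prob_post_min,wear_recovery_days Parameters of the default
#'   post-op wear curve.
#' @param wear_conc Beta concentration of patient-level wear-probability
#'   heterogeneity (mean-preserving; larger = more homogeneous).
#' @param clip_forget_prob Extra daily non-wear probability for clip
#'   devices.
#' @param clip_postop_window_shrink Evening hours removed from clip
#'   wearers' wear window in days 0-13 (half that in days 14-27).
#' @param wear_start_mean,wear_start_sd,wear_end_mean,wear_end_sd Daily
#'   wear-window start/end draws, in clock hours.
#' @param diurnal_template 24 non-negative weights (normalised internally)
#'   giving the share of daily steps per clock hour; `NULL` for a default
#'   waking-hours profile peaking late morning and afternoon.
#' @param base_daily_steps Mean steps on a fully worn presurgery day.
#' @param activity_sdlog Log-normal SD of the patient-level activity
#'   multiplier (mean 1).
#' @param dispersion Negative-binomial size for hourly counts (smaller =
#'   burstier; Poisson is the large-size limit).
#' @param bout_scale Governs hour-level zero inflation: an hour with target
#'   mean `mu` is active with probability `1 - exp(-mu / bout_scale)`.
#' @param incidental_wrist,incidental_clip Mean incidental steps per worn
#'   hour registered from arm/torso movement, by device placement.
#'   Incidental registration does not dip with surgery — a wrist tracker
#'   picks up arm movement even in an immobile patient — which is what
#'   keeps the wrist group's criteria in close agreement through recovery.
#' @param surgery_dip Multiplicative activity reduction at day 0, in
#'   \[0, 1\] (0.85 = activity falls to 15% of baseline).
#' @param recovery_days Days from surgery back to baseline activity.
#' @param recovery_shape `"linear"` or `"exponential"` ramp.
#' @param overshoot Post-recovery activity multiplier (>1 allows exceeding
#'   the presurgery level).
#' @param device_mix Fraction of wrist-worn devices.
#' @param age_mean,age_sd,age_range,female_prob,bmi_mean,bmi_sd,bmi_range,asa_probs
#'   Demographic sampling parameters (`asa_probs` over classes 1..5).
#' @return A validated `pw_sim_config` list.
#' @export
sim_config <- function(n_patients = 20L,
                       seed = 1L,
                       wear_prob_pre = 0.9,
                       wear_prob_post_curve = NULL,
                       wear_prob_post_min = 0.8,
                       wear_recovery_days = 28L,
                       wear_conc = 60,
                       clip_forget_prob = 0.12,
                       clip_postop_window_shrink = 6,
                       wear_start_mean = 7, wear_start_sd = 1,
                       wear_end_mean = 22, wear_end_sd = 1,
                       diurnal_template = NULL,
                       base_daily_steps = 4000,
                       activity_sdlog = 0.3,
                       dispersion = 0.3,
                       bout_scale = 150,
                       incidental_wrist = 1.5,
                       incidental_clip = 0.2,
                       surgery_dip = 0.85,
                       recovery_days = 35L,
                       recovery_shape = c("linear", "exponential"),
                       overshoot = 1,
                       device_mix = 0.6,
                       age_mean = 64.5, age_sd = 8.94, age_range = c(37, 85),
                       female_prob = 0.65,
                       bmi_mean = 30, bmi_sd = 4, bmi_range = c(18, 45),
                       asa_probs = c(0.05, 0.9, 0.05, 0, 0)) {
  recovery_shape <- match.arg(recovery_shape)
  if (is.null(diurnal_template)) {
    diurnal_template <- c(rep(0, 6),                    # 00-05: asleep
                          0.02, 0.05, 0.07, 0.08, 0.08, 0.08,  # 06-11
                          0.07, 0.07, 0.08, 0.08, 0.08, 0.08,  # 12-17
                          0.07, 0.05, 0.04, 0.03, 0.02, 0.005) # 18-23
  }
  stopifnot(length(diurnal_template) == 24L, all(diurnal_template >= 0),
            sum(diurnal_template) > 0)
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              wear_prob_pre = wear_prob_pre,
              wear_prob_post_curve = wear_prob_post_curve,
              wear_prob_post_min = wear_prob_post_min,
              wear_recovery_days = as.integer(wear_recovery_days),
              wear_conc = wear_conc,
              clip_forget_prob = clip_forget_prob,
              clip_postop_window_shrink = clip_postop_window_shrink,
              wear_start_mean = wear_start_mean, wear_start_sd = wear_start_sd,
              wear_end_mean = wear_end_mean, wear_end_sd = wear_end_sd,
              diurnal_template = diurnal_template / sum(diurnal_template),
              base_daily_steps = base_daily_steps,
              activity_sdlog = activity_sdlog,
              dispersion = dispersion, bout_scale = bout_scale,
              incidental_wrist = incidental_wrist,
              incidental_clip = incidental_clip,
              surgery_dip = surgery_dip,
              recovery_days = as.integer(recovery_days),
              recovery_shape = recovery_shape, overshoot = overshoot,
              device_mix = device_mix,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              female_prob = female_prob,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_range = bmi_range,
              asa_probs = asa_probs)
  validate_sim_config(cfg)
  structure(cfg, class = "pw_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_patients <= 0L) stop("n_patients must be positive", call. = FALSE)
  probs <- c(cfg$wear_prob_pre, cfg$wear_prob_post_min, cfg$clip_forget_prob,
             cfg$device_mix, cfg$female_prob, cfg$wear_prob_post_curve)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$surgery_dip < 0 || cfg$surgery_dip > 1) {
    stop("surgery_dip must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$recovery_days < 0L) stop("recovery_days must be >= 0", call. = FALSE)
  if (!is.null(cfg$wear_prob_post_curve) &&
      length(cfg$wear_prob_post_curve) != 43L) {
    stop("wear_prob_post_curve must have 43 values (days 0..42)", call. = FALSE)
  }
  invisible(cfg)
}

#' Surgery dip-and-recovery multiplier
#'
#' Activity multiplier applied to the diurnal mean on each perioperative
#' day: 1 before surgery, `1 - surgery_dip` on the surgery day, ramping
#' back to `overshoot` (default 1) by `recovery_days` days after surgery.
#'
#' @param day_index Integer day index (vectorised), in -14..42.
#' @inheritParams sim_config
#' @param shape `"linear"` or `"exponential"` recovery.
#' @return Numeric multiplier(s) in \[0, Inf).
#' @export
#' @examples
#' surgery_multiplier(14, surgery_dip = 0.6, recovery_days = 28)  # 0.7
surgery_multiplier <- function(day_index, surgery_dip, recovery_days,
                               shape = c("linear", "exponential"),
                               overshoot = 1) {
  shape <- match.arg(shape)
  if (surgery_dip < 0 || surgery_dip > 1) {
    stop("surgery_dip must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(day_index >= DAY_MIN & day_index <= DAY_MAX))
  floor_mult <- 1 - surgery_dip
  out <- rep(1, length(day_index))
  post <- day_index >= 0
  if (any(post)) {
    d <- day_index[post]
    if (recovery_days == 0L) {
      m <- ifelse(d == 0, floor_mult, overshoot)
    } else if (shape == "linear") {
      frac <- pmin(d / recovery_days, 1)
      m <- floor_mult + (overshoot - floor_mult) * frac
    } else {
      # ~95% recovered at recovery_days
      m <- overshoot - (overshoot - floor_mult) * exp(-3 * d / recovery_days)
    }
    out[post] <- m
  }
  out
}

default_post_wear_curve <- function(cfg) {
  d <- 0:42
  ramp <- pmin(d / max(cfg$wear_recovery_days, 1L), 1)
  curve <- cfg$wear_prob_post_min +
    (cfg$wear_prob_pre - cfg$wear_prob_post_min) * ramp
  # day-0 bump: hospital staff remind patients to wear the tracker
  curve[1] <- min(1, max(curve[1], cfg$wear_prob_pre + 0.05))
  curve
}

draw_patient_latent <- function(cfg, i) {
  device <- if (stats::runif(1) < cfg$device_mix) "wrist" else "clip"
  shift <- stats::qlogis(min(max(cfg$wear_prob_pre, 1e-6), 1 - 1e-6))
  wear_pre_i <- stats::rbeta(1, cfg$wear_prob_pre * cfg$wear_conc,
                             (1 - cfg$wear_prob_pre) * cfg$wear_conc)
  list(
    patient_id = sprintf("P%02d", i),
    device = device,
    activity_mult = stats::rnorm(1) |> (\(z) exp(z * cfg$activity_sdlog -
                                                   cfg$activity_sdlog^2 / 2))(),
    wear_prob_pre = wear_pre_i,
    # patient-level wear offset on the logit scale, reused post-op so the
    # same patients stay forgetful throughout
    wear_logit_offset = stats::qlogis(min(max(wear_pre_i, 1e-6), 1 - 1e-6)) - shift,
    age = min(max(stats::rnorm(1, cfg$age_mean, cfg$age_sd),
                  cfg$age_range[1]), cfg$age_range[2]),
    gender = if (stats::runif(1) < cfg$female_prob) "F" else "M",
    bmi = min(max(stats::rnorm(1, cfg$bmi_mean, cfg$bmi_sd),
                  cfg$bmi_range[1]), cfg$bmi_range[2]),
    asa = sample(1:5, 1, prob = cfg$asa_probs)
  )
}

#' Simulate one patient timeline
#'
#' @param cfg A `pw_sim_config`.
#' @param latent Patient latent draw (as stored in a cohort's `truth`);
#'   `NULL` draws a fresh one from the current RNG state.
#' @param surgery_date Calendar surgery date for the metadata row.
#' @return A `pw_timeline`.
#' @export
simulate_patient <- function(cfg, latent = NULL,
                             surgery_date = as.Date("2017-06-01")) {
  validate_sim_config(cfg)
  if (is.null(latent)) latent <- draw_patient_latent(cfg, 0L)
  post_curve <- cfg$wear_prob_post_curve
  if (is.null(post_curve)) post_curve <- default_post_wear_curve(cfg)
  hourly <- matrix(0L, 57L, 24L)
  minutes <- integer(57L)
  for (i in seq_len(57L)) {
    d <- day_indices()[i]
    base_p <- if (d < 0) cfg$wear_prob_pre else post_curve[d + 1L]
    p_worn <- stats::plogis(stats::qlogis(min(max(base_p, 1e-6), 1 - 1e-6)) +
                              latent$wear_logit_offset)
    if (latent$device == "clip") p_worn <- max(0, p_worn - cfg$clip_forget_prob)
    if (stats::rbinom(1, 1, p_worn) == 0L) next
    w_start <- round(stats::rnorm(1, cfg$wear_start_mean, cfg$wear_start_sd))
    w_end <- round(stats::rnorm(1, cfg$wear_end_mean, cfg$wear_end_sd))
    if (latent$device == "clip") {
      shrink <- if (d >= 0 && d <= 13) cfg$clip_postop_window_shrink
                else if (d >= 14 && d <= 27) cfg$clip_postop_window_shrink / 2
                else 0
      w_end <- w_end - shrink
    }
    w_start <- min(max(w_start, 0), 22)
    w_end <- max(min(w_end, 23), w_start + 1)
    hours <- seq.int(w_start, w_end)
    mult <- surgery_multiplier(d, cfg$surgery_dip, cfg$recovery_days,
                               cfg$recovery_shape, cfg$overshoot)
    mu <- cfg$base_daily_steps * latent$activity_mult *
      cfg$diurnal_template[hours + 1L] * mult
    p_active <- 1 - exp(-mu / cfg$bout_scale)
    on <- stats::rbinom(length(hours), 1L, p_active)
    counts <- integer(length(hours))
    act <- on == 1L & mu > 0
    if (any(act)) {
      counts[act] <- stats::rnbinom(sum(act),
                                    mu = mu[act] / p_active[act],
                                    size = cfg$dispersion)
    }
    # incidental registration over the worn window, independent of the dip
    incid_rate <- if (latent$device == "wrist") cfg$incidental_wrist
                  else cfg$incidental_clip
    counts <- counts + stats::rpois(length(hours), incid_rate)
    hourly[i, hours + 1L] <- counts
    minutes[i] <- 60L * length(hours)
  }
  meta <- data.frame(patient_id = latent$patient_id,
                     surgery_date = surgery_date,
                     age = latent$age, gender = latent$gender,
                     bmi = latent$bmi, asa = latent$asa,
                     device = latent$device,
                     stringsAsFactors = FALSE)
  new_timeline(meta, hourly, minutes)
}

#' Simulate a cohort
#'
#' Draws metadata and latent behaviour for `n_patients` patients and
#' simulates every timeline. Identical `cfg` (including `seed`) gives a
#' bit-identical cohort. The latent truth is retained for
#' parameter-recovery tests.
#'
#' @param cfg A `pw_sim_config`.
#' @return A `pw_sim_cohort`: `cohort` (a `pw_cohort`), `truth` (list of
#'   per-patient latent draws) and `config`.
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  latents <- lapply(seq_len(cfg$n_patients), function(i) draw_patient_latent(cfg, i))
  surgery_dates <- as.Date("2017-03-01") + 7L * (seq_len(cfg$n_patients) - 1L)
  timelines <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    timelines[[i]] <- simulate_patient(cfg, latents[[i]], surgery_dates[i])
  }
  names(timelines) <- vapply(latents, `[[`, "", "patient_id")
  meta <- do.call(rbind, lapply(timelines, function(tl) tl$meta))
  rownames(meta) <- NULL
  cohort <- structure(list(timelines = timelines, meta = meta),
                      class = "pw_cohort")
  structure(list(cohort = cohort, truth = latents, config = cfg),
            class = "pw_sim_cohort")
}

#' @export
print.pw_sim_cohort <- function(x, ...) {
  cat("<pw_sim_cohort> seed", x$config$seed, "\n")
  print(x$cohort)
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the same tidy hour-resolution steps CSV the ingest module reads
#' (round-trip tested), the metadata CSV, and the latent truth as JSON.
#' Only hours with nonzero counts are written; absent rows are non-wear.
#'
#' @param sim A `pw_sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_sim_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "pw_sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- cohort_long(sim$cohort)
  meta <- sim$cohort$meta
  long <- merge(long,
                data.table::as.data.table(meta)[, .(patient_id, surgery_date)],
                by = "patient_id")
  long <- long[steps > 0]
  long[, timestamp := sprintf("%s %02d:00", format(surgery_date + day_index), hour)]
  steps_path <- file.path(dir, "steps.csv")
  meta_path <- file.path(dir, "meta.csv")
  truth_path <- file.path(dir, "truth.json")
  data.table::fwrite(long[order(patient_id, day_index, hour),
                          .(patient_id, timestamp, steps)], steps_path)
  utils::write.csv(meta, meta_path, row.names = FALSE)
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(steps = steps_path, meta = meta_path, truth = truth_path))
}
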