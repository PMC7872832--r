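# Figure builders. All numbers plotted come verbatim from the aggregation
# tables; tests assert on those tables and only smoke-test rendering.

save_plot <- function(p, out, width, height, dpi) {
  if (is.null(out)) return(invisible(NULL))
  ggplot2::ggsave(out, plot = p, width = width, height = height, dpi = dpi)
  invisible(out)
}

#' Hour-by-day activity heatmap
#'
#' One patient's perioperative record as a 57 x 24 grid: day index on the
#' x-axis (-14..42), clock hour on the y-axis, cell shade linear in the
#' hourly step count from white (0) to black (clamped at 500+), with a red
#' vertical rule at the surgery day.
#'
#' @param timeline A `pw_timeline`.
#' @param out Optional output path (`.png`/`.svg`/`.pdf` by extension).
#' @param clamp Step count mapped to full black (default 500).
#' @param width,height,dpi Device settings for `out`.
#' @return The ggplot object, invisibly if written to `out`.
#' @export
activity_heatmap <- function(timeline, out = NULL, clamp = 500,
                             width = 9, height = 4, dpi = 150) {
  stopifnot(inherits(timeline, "pw_timeline"))
  df <- data.frame(day_index = rep(day_indices(), times = 24L),
                   hour = rep(0:23, each = 57L),
                   steps = as.vector(timeline$hourly))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = day_index, y = hour, fill = steps)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, clamp),
                                 oob = scales::squish,
                                 name = "steps/h") +
    ggplot2::geom_vline(xintercept = 0, colour = "red", linewidth = 0.6) +
    ggplot2::scale_x_continuous(limits = c(DAY_MIN - 0.5, DAY_MAX + 0.5),
                                expand = c(0, 0)) +
    ggplot2::scale_y_continuous(breaks = seq(0, 23, 4), expand = c(0, 0)) +
    ggplot2::labs(x = "perioperative day", y = "hour of day",
                  title = paste("Patient", timeline$meta$patient_id)) +
    ggplot2::theme_minimal()
  if (!is.null(out)) { save_plot(p, out, width, height, dpi); return(invisible(p)) }
  p
}

#' Daily compliance with mean +/- SD band
#'
#' The across-criteria mean daily compliance rate as a line, with a shaded
#' band of one between-criteria standard deviation (clipped to \[0, 1\])
#' and the red surgery-day rule.
#'
#' @param series A [deviation_series()] table covering all 57 days.
#' @inheritParams activity_heatmap
#' @return The ggplot object.
#' @export
daily_compliance_plot <- function(series, out = NULL,
                                  width = 9, height = 4, dpi = 150) {
  stopifnot(all(c("day_index", "mean", "sd") %in% names(series)))
  if (!setequal(series$day_index, day_indices())) {
    stop("series must cover all 57 day indices", call. = FALSE)
  }
  df <- as.data.frame(series)
  df$lo <- pmax(0, df$mean - df$sd)
  df$hi <- pmin(1, df$mean + df$sd)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = day_index, y = mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(colour = "grey20", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, colour = "red", linewidth = 0.6) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "perioperative day", y = "proportion compliant") +
    ggplot2::theme_minimal()
  if (!is.null(out)) { save_plot(p, out, width, height, dpi); return(invisible(p)) }
  p
}

#' Per-criterion daily compliance overlay
#'
#' Five labelled lines, one per criterion, over the perioperative window.
#'
#' @param rates A [daily_sample_rate()] table.
#' @inheritParams activity_heatmap
#' @return The ggplot object.
#' @export
criteria_overlay_plot <- function(rates, out = NULL,
                                  width = 9, height = 4, dpi = 150) {
  stopifnot(all(c("day_index", "criterion", "rate") %in% names(rates)))
  df <- as.data.frame(rates)
  df$criterion <- factor(df$criterion,
                         levels = intersect(c(builtin_criteria(),
                                              unique(df$criterion)),
                                            unique(df$criterion)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = day_index, y = rate,
                                        colour = criterion)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = 0, colour = "red", linewidth = 0.6) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "perioperative day", y = "proportion compliant") +
    ggplot2::theme_minimal()
  if (!is.null(out)) { save_plot(p, out, width, height, dpi); return(invisible(p)) }
  p
}

#' Device-stratified compliance panels
#'
#' For each device group (clip, wrist): the per-criterion daily rates and
#' the between-criteria deviation series, as a faceted multi-panel figure.
#' An empty device group is skipped with a warning.
#'
#' @param matrix A compliance matrix from [evaluate_matrix()].
#' @param meta Patient metadata with `device`.
#' @inheritParams across_criteria_stats
#' @inheritParams activity_heatmap
#' @return The ggplot object, or `NULL` if no group has data.
#' @export
device_panels <- function(matrix, meta, out = NULL,
                          sd_denominator = c("sample", "population"),
                          width = 10, height = 6, dpi = 150) {
  sd_denominator <- match.arg(sd_denominator)
  check_matrix(matrix)
  dt <- data.table::as.data.table(matrix)
  parts <- list()
  for (dev in c("clip", "wrist")) {
    ids <- meta$patient_id[meta$device == dev]
    sub <- dt[patient_id %in% ids]
    if (nrow(sub) == 0L) {
      warning("no ", dev, " patients: panel skipped", call. = FALSE)
      next
    }
    rates <- daily_sample_rate(sub)
    rates[, `:=`(device = dev, panel = paste(dev, "daily rates"))]
    dev_series <- deviation_series(sub, sd_denominator)
    dev_series[, `:=`(criterion = "between-criteria SD", rate = sd,
                      device = dev, panel = paste(dev, "deviation"))]
    parts[[length(parts) + 1L]] <- rates
    parts[[length(parts) + 1L]] <- dev_series[, .(day_index, criterion, rate,
                                                  device, panel)]
  }
  if (!length(parts)) return(NULL)
  df <- as.data.frame(data.table::rbindlist(parts, fill = TRUE))
  df$panel <- factor(df$panel, levels = unique(df$panel))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = day_index, y = rate,
                                        colour = criterion)) +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::geom_vline(xintercept = 0, colour = "red", linewidth = 0.5) +
    ggplot2::facet_wrap(~panel, ncol = 2) +
    ggplot2::coord_cartesian(xlim = c(DAY_MIN, DAY_MAX)) +
    ggplot2::labs(x = "perioperative day", y = "proportion / SD") +
    ggplot2::theme_minimal()
  if (!is.null(out)) { save_plot(p, out, width, height, dpi); return(invisible(p)) }
  p
}
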