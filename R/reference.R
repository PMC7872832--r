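# Published reference values bundled with the package.

#' Reference whole-period compliance summary
#'
#' The reported per-criterion summary of whole-period compliance (mean, SD,
#' minimum, maximum, range over patients) for the motivating 20-patient
#' total-knee-arthroplasty cohort. These are published reference values for
#' comparison and sanity checks; they are not computed by this package.
#'
#' @return data.frame with columns `criterion`, `mean`, `sd`, `min`,
#'   `max`, `range`.
#' @export
reference_summary <- function() {
  path <- system.file("extdata", "reference_summary.csv", package = "periwear",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Lenient-vs-strict compliance gap
#'
#' Difference in mean whole-period compliance between the most lenient
#' criterion (`gt0_steps`) and the strictest (`ge10_hours`), in percentage
#' points.
#'
#' @param summary A summary table with `criterion` and `mean` columns
#'   (default: the bundled [reference_summary()]).
#' @return Numeric scalar, percentage points.
#' @export
#' @examples
#' lenient_strict_gap()  # 24
lenient_strict_gap <- function(summary = reference_summary()) {
  means <- stats::setNames(summary$mean, summary$criterion)
  stopifnot(all(c("gt0_steps", "ge10_hours") %in% names(means)))
  100 * (means[["gt0_steps"]] - means[["ge10_hours"]])
}
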