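# The five valid-day criteria, a user-extensible registry, and the
# cohort-level compliance matrix.
#
# Every predicate consumes a 24-element clock-hour step vector; the only one
# that can look beyond the calendar day is 3-a-day, whose evening window
# (3 pm - 3 am) crosses midnight and, by default, claims hours 0-2 of the
# following day.

check_hourly <- function(hourly) {
  stopifnot(length(hourly) == 24L, all(hourly >= 0))
  invisible(hourly)
}

#' Valid-day criteria
#'
#' Each predicate decides whether one patient-day counts as a valid day of
#' tracker wear:
#' \describe{
#'   \item{`valid_gt0()`}{at least one step anywhere in the day.}
#'   \item{`valid_gt500()`}{strictly more than 500 steps in the day.}
#'   \item{`valid_ge10_hours()`}{at least one step in 10 or more distinct
#'     clock hours.}
#'   \item{`valid_three_a_day()`}{at least one step in each of three
#'     anchored windows: 3 am-11 am, 11 am-3 pm, and 3 pm-3 am. The third
#'     window wraps into hours 0-2 of the next day when `next_day_early`
#'     is supplied and `wrap = TRUE`; otherwise it truncates at midnight.}
#'   \item{`valid_three_of_four()`}{at least one step in 3 of the 4
#'     six-hour windows 12 am-6 am, 6 am-12 pm, 12 pm-6 pm, 6 pm-12 am.}
#' }
#' Window bounds are half-open on clock-hour labels, e.g. 3 am-11 am means
#' hours 3 through 10.
#'
#' @param hourly Numeric vector of 24 non-negative step counts (hour 0-23).
#' @param next_day_early For `valid_three_a_day()`: counts for hours 0-2 of
#'   the following day, or `NULL` on the final day of the window.
#' @param wrap Should the 3 pm-3 am window claim next-day hours 0-2?
#' @return Logical scalar.
#' @name criteria
NULL

#' @rdname criteria
#' @export
valid_gt0 <- function(hourly) {
  check_hourly(hourly)
  sum(hourly) >= 1
}

#' @rdname criteria
#' @export
valid_gt500 <- function(hourly) {
  check_hourly(hourly)
  sum(hourly) > 500
}

#' @rdname criteria
#' @export
valid_ge10_hours <- function(hourly) {
  check_hourly(hourly)
  sum(hourly >= 1) >= 10L
}

#' @rdname criteria
#' @export
valid_three_a_day <- function(hourly, next_day_early = NULL, wrap = TRUE) {
  check_hourly(hourly)
  morning <- sum(hourly[4:11])    # hours 3-10
  midday  <- sum(hourly[12:15])   # hours 11-14
  evening <- sum(hourly[16:24])   # hours 15-23
  if (wrap && !is.null(next_day_early)) {
    stopifnot(length(next_day_early) == 3L)
    evening <- evening + sum(next_day_early)
  }
  morning >= 1 && midday >= 1 && evening >= 1
}

#' @rdname criteria
#' @export
valid_three_of_four <- function(hourly) {
  check_hourly(hourly)
  active <- c(sum(hourly[1:6]), sum(hourly[7:12]),
              sum(hourly[13:18]), sum(hourly[19:24])) >= 1
  sum(active) >= 3L
}

# registry: built-ins are fixed, user criteria may be added alongside
.criteria_registry <- new.env(parent = emptyenv())

BUILTIN_CRITERIA <- c("gt0_steps", "gt500_steps", "ge10_hours",
                      "three_a_day", "three_of_four")

register_builtin <- function(id, fun, needs_next_day = FALSE) {
  assign(id, list(fun = fun, needs_next_day = needs_next_day,
                  builtin = TRUE), envir = .criteria_registry)
}
register_builtin("gt0_steps", function(hourly, ...) valid_gt0(hourly))
register_builtin("gt500_steps", function(hourly, ...) valid_gt500(hourly))
register_builtin("ge10_hours", function(hourly, ...) valid_ge10_hours(hourly))
register_builtin("three_a_day",
                 function(hourly, next_day_early = NULL, wrap = TRUE)
                   valid_three_a_day(hourly, next_day_early, wrap),
                 needs_next_day = TRUE)
register_builtin("three_of_four", function(hourly, ...) valid_three_of_four(hourly))

#' Criterion registry
#'
#' The five built-in criteria are always available; additional criteria can
#' be registered as predicates on the 24-hour vector. Built-ins cannot be
#' replaced.
#'
#' @param id Criterion identifier.
#' @param fun Predicate `function(hourly, ...) -> logical`.
#' @param needs_next_day Does the predicate use the `next_day_early`
#'   argument (first three hours of the following day)?
#' @return `register_criterion()` returns `id` invisibly;
#'   `list_criteria()` the registered ids (built-ins first);
#'   `builtin_criteria()` the five canonical ids.
#' @export
register_criterion <- function(id, fun, needs_next_day = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, is.function(fun))
  if (id %in% BUILTIN_CRITERIA) {
    stop("cannot replace built-in criterion '", id, "'", call. = FALSE)
  }
  assign(id, list(fun = fun, needs_next_day = needs_next_day, builtin = FALSE),
         envir = .criteria_registry)
  invisible(id)
}

#' @rdname register_criterion
#' @export
list_criteria <- function() {
  ids <- ls(.criteria_registry)
  c(BUILTIN_CRITERIA, sort(setdiff(ids, BUILTIN_CRITERIA)))
}

#' @rdname register_criterion
#' @export
builtin_criteria <- function() BUILTIN_CRITERIA

get_criterion <- function(id) {
  if (!exists(id, envir = .criteria_registry, inherits = FALSE)) {
    stop("unknown criterion '", id, "'", call. = FALSE)
  }
  get(id, envir = .criteria_registry, inherits = FALSE)
}

#' Evaluate the compliance matrix for a cohort
#'
#' Applies each criterion to every patient-day, producing the fully
#' populated long-format validity table all downstream summaries consume.
#' All-zero (non-wear) days are invalid under every criterion by
#' construction.
#'
#' @param cohort A `pw_cohort`.
#' @param criteria Character vector of registered criterion ids.
#' @param three_a_day_wrap Should the 3-a-day evening window wrap into the
#'   next day (default) or truncate at midnight?
#' @return A `pw_compliance` data.table with columns `patient_id`,
#'   `day_index`, `criterion` and logical `valid`; one row per
#'   patient-day-criterion.
#' @export
evaluate_matrix <- function(cohort, criteria = builtin_criteria(),
                            three_a_day_wrap = TRUE) {
  stopifnot(inherits(cohort, "pw_cohort"))
  defs <- lapply(criteria, get_criterion)
  names(defs) <- criteria
  if (length(cohort$timelines) == 0L) {
    warning("empty cohort: compliance matrix has no rows", call. = FALSE)
    out <- data.table::data.table(patient_id = character(),
                                  day_index = integer(),
                                  criterion = character(), valid = logical())
    class(out) <- c("pw_compliance", class(out))
    return(out)
  }
  per_patient <- lapply(cohort$timelines, function(tl) {
    h <- tl$hourly
    vals <- lapply(defs, function(def) {
      vapply(seq_len(57L), function(i) {
        if (def$needs_next_day && i < 57L) {
          def$fun(h[i, ], next_day_early = h[i + 1L, 1:3],
                  wrap = three_a_day_wrap)
        } else if (def$needs_next_day) {
          def$fun(h[i, ], next_day_early = NULL, wrap = three_a_day_wrap)
        } else {
          def$fun(h[i, ])
        }
      }, logical(1))
    })
    data.table::data.table(
      patient_id = tl$meta$patient_id,
      day_index = rep(day_indices(), times = length(defs)),
      criterion = rep(names(defs), each = 57L),
      valid = unlist(vals, use.names = FALSE)
    )
  })
  out <- data.table::rbindlist(per_patient)
  data.table::setkeyv(out, c("patient_id", "day_index", "criterion"))
  class(out) <- c("pw_compliance", class(out))
  out[]
}
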