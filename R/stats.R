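# Correlation tests and the subject-random-intercept mixed model relating
# compliance (and between-criteria deviation) to device placement, stage
# and demographics.

cor_test_core <- function(x, y, method) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined: zero variance in input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(r = r, p = p, statistic = t, df = df, n = n, method = method),
            class = "pw_cor")
}

#' @export
print.pw_cor <- function(x, ...) {
  cat(sprintf("%s: r = %.3f, t(%d) = %.3f, p = %.4g (n = %d)\n",
              x$method, x$r, x$df, x$statistic, x$p, x$n))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Two-sided test via `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (pairwise-complete, n >= 3,
#'   nonzero variance).
#' @return A `pw_cor` list: `r`, `p`, `statistic`, `df`, `n`.
#' @export
pearson <- function(x, y) cor_test_core(x, y, "Pearson correlation")

#' Point-biserial correlation
#'
#' Correlation between a dichotomous 0/1 variable and a continuous one:
#' numerically identical to the Pearson correlation of the 0/1 coding with
#' `x`, with the same t-based two-sided p-value.
#'
#' @param binary Vector of 0/1 codes (both groups nonempty).
#' @param x Numeric vector.
#' @return A `pw_cor` list as for [pearson()].
#' @export
point_biserial <- function(binary, x) {
  if (!all(binary %in% c(0, 1))) {
    stop("binary must contain only 0/1 codes", call. = FALSE)
  }
  if (length(unique(binary)) < 2L) {
    stop("both groups of the dichotomy must be nonempty", call. = FALSE)
  }
  cor_test_core(as.numeric(binary), x, "Point-biserial correlation")
}

#' Long modelling table of stage compliance
#'
#' One row per patient x criterion x stage, joined to the demographic and
#' device covariates, in deterministic (patient, criterion, stage) order —
#' the input to [stage_effect_model()].
#'
#' @param stages Table from [stage_compliance()].
#' @param meta Patient metadata.
#' @return data.table with `patient_id`, `criterion`, `stage`,
#'   `compliance`, `device`, `age`, `gender`, `bmi`; `criterion` and
#'   `stage` are factors with levels in canonical order.
#' @export
build_stage_table <- function(stages, meta) {
  stopifnot(all(c("patient_id", "stage", "criterion", "value") %in% names(stages)))
  st <- data.table::as.data.table(stages)
  counts <- st[, .N, by = patient_id]
  expect_n <- length(unique(st$criterion)) * length(unique(st$stage))
  bad <- counts[N != expect_n]
  if (nrow(bad)) {
    stop("incomplete stage summaries for patient(s): ",
         paste(bad$patient_id, collapse = ", "), call. = FALSE)
  }
  m <- data.table::as.data.table(meta)[, .(patient_id, device, age, gender, bmi)]
  out <- merge(st, m, by = "patient_id")
  data.table::setnames(out, "value", "compliance")
  crit_levels <- intersect(c(builtin_criteria(),
                             sort(unique(out$criterion))), unique(out$criterion))
  out[, criterion := factor(criterion, levels = crit_levels)]
  out[, stage := factor(stage, levels = stage_names())]
  out[, device := factor(device, levels = c("clip", "wrist"))]
  data.table::setcolorder(out, c("patient_id", "criterion", "stage",
                                 "compliance", "device", "age", "gender", "bmi"))
  out[order(patient_id, criterion, stage)]
}

#' Mixed model for stage-wise compliance
#'
#' Fits a linear model with the requested fixed effects and a patient-level
#' random intercept (REML by default, via [lme4::lmer()]). The report
#' carries per-coefficient Wald-z p-values and, for each droppable fixed
#' term, a likelihood-ratio omnibus test computed on an ML refit.
#' Categorical covariates use treatment coding against the first factor
#' level (recorded in the report).
#'
#' @param table A modelling table such as from [build_stage_table()], or
#'   any data.frame containing the response and terms.
#' @param formula Fixed-effects formula, e.g.
#'   `compliance ~ criterion * stage + device + age`. The random intercept
#'   is added automatically.
#' @param subject Column holding the grouping id (default `"patient_id"`).
#' @param reml Fit by REML (default) or ML.
#' @return A `pw_effect_report`: `coefficients` (term, estimate, se,
#'   statistic, p), `omnibus` (term, df, LRT chisq, p), `coding` notes and
#'   the underlying `model`.
#' @export
stage_effect_model <- function(table, formula, subject = "patient_id",
                               reml = TRUE) {
  stopifnot(inherits(formula, "formula"))
  dat <- as.data.frame(table)
  vars <- all.vars(formula)
  missing_vars <- setdiff(c(vars, subject), names(dat))
  if (length(missing_vars)) {
    stop("term(s) not in table: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  mm <- stats::model.matrix(formula, dat)
  if (qr(mm)$rank < ncol(mm)) {
    aliased <- colnames(mm)[-seq_len(qr(mm)$rank)]
    stop("rank-deficient fixed-effect design; aliased: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  full <- stats::as.formula(paste(deparse(formula, width.cutoff = 500L),
                                  "+ (1 |", subject, ")"))
  fit <- lme4::lmer(full, data = dat, REML = reml)
  co <- tryCatch(as.data.frame(summary(fit)$coefficients),
                 error = function(e) NULL)
  if (is.null(co)) {
    # degenerate fit (e.g. constant response): report point estimates only
    fe <- lme4::fixef(fit)
    co <- data.frame(Estimate = fe, `Std. Error` = NA_real_,
                     `t value` = NA_real_, row.names = names(fe),
                     check.names = FALSE)
  }
  coef_tab <- data.frame(term = rownames(co),
                         estimate = co[, "Estimate"],
                         se = co[, "Std. Error"],
                         statistic = co[, "t value"],
                         p = 2 * stats::pnorm(-abs(co[, "t value"])),
                         row.names = NULL)
  # omnibus per droppable term: LRT on an ML refit
  fit_ml <- if (reml) stats::update(fit, REML = FALSE) else fit
  omnibus <- tryCatch({
    d1 <- stats::drop1(fit_ml, test = "Chisq")
    terms_d <- rownames(d1)[-1L]
    data.frame(term = terms_d,
               df = d1$npar[-1L],
               chisq = d1$LRT[-1L],
               p = d1$`Pr(Chi)`[-1L],
               row.names = NULL)
  }, error = function(e) {
    warning("omnibus LRT unavailable: ", conditionMessage(e), call. = FALSE)
    NULL
  })
  structure(list(coefficients = coef_tab, omnibus = omnibus, model = fit,
                 reml = reml,
                 coding = paste("treatment contrasts; reference level =",
                                "first factor level; coefficient p-values",
                                "are Wald-z; omnibus tests are ML",
                                "likelihood ratios")),
            class = "pw_effect_report")
}

#' @export
print.pw_effect_report <- function(x, digits = 4, ...) {
  cat("Linear mixed model (patient random intercept,",
      if (x$reml) "REML" else "ML", "fit)\n")
  cat(x$coding, "\n\nFixed effects:\n")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  if (!is.null(x$omnibus)) {
    cat("\nOmnibus likelihood-ratio tests:\n")
    print(format(x$omnibus, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Flat CSV/JSON export of an effect report
#'
#' @param report A `pw_effect_report`.
#' @param path Output path; `.json` selects JSON, anything else CSV.
#' @return The path, invisibly.
#' @export
write_effect_report <- function(report, path) {
  stopifnot(inherits(report, "pw_effect_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(coefficients = report$coefficients,
                              omnibus = report$omnibus,
                              coding = report$coding),
                         path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    utils::write.csv(report$coefficients, path, row.names = FALSE)
  }
  invisible(path)
}
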