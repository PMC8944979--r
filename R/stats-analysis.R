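#' Group summaries of condylar volume by pattern class
#'
#' Per-level condyle count, median, mean, min, max and sample SD (n - 1) of
#' `volume_mm3`, for each of the three classification axes. Empty levels
#' are reported with count 0.
#'
#' @param data Cohort data frame; label columns are computed with
#'   [classify_pattern()] if absent.
#' @return Data frame with columns `variable`, `level`, `n_condyles`,
#'   `median`, `mean`, `min`, `max`, `sd`.
#' @export
group_summaries <- function(data) {
  validate_cohort(data)
  label_cols <- c("skeletal_class", "divergence_class", "growth_class")
  if (!all(label_cols %in% names(data))) {
    data <- add_pattern_labels(data)
  }
  out <- do.call(rbind, lapply(label_cols, function(axis) {
    f <- data[[axis]]
    do.call(rbind, lapply(levels(f), function(lv) {
      v <- data$volume_mm3[f == lv]
      if (length(v) == 0L) {
        data.frame(variable = axis, level = lv, n_condyles = 0L,
                   median = NA_real_, mean = NA_real_, min = NA_real_,
                   max = NA_real_, sd = NA_real_)
      } else {
        data.frame(variable = axis, level = lv, n_condyles = length(v),
                   median = stats::median(v), mean = mean(v),
                   min = min(v), max = max(v),
                   sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
      }
    }))
  }))
  rownames(out) <- NULL
  out
}

fit_or_note <- function(data, covariates, outcome, subject) {
  tryCatch(
    fit_random_intercept(data, outcome = outcome, covariates = covariates,
                         subject = subject),
    error = function(e) {
      structure(list(message = conditionMessage(e)), class = "ri_unavailable")
    }
  )
}

#' Crude, adjusted and sex-stratified two-level study analysis
#'
#' Runs the full regression battery on a cohort table: for each continuous
#' cephalometric variable (ANB, divergence, total gonial angle) a crude
#' random-intercept fit, a fit adjusted by sex and age, and per-sex fits
#' adjusted by age; plus categorical fits on the pattern classes with the
#' clinical reference groups (Class I, normodivergent, normal growth),
#' crude and adjusted. Strata with fewer than 3 subjects are reported as
#' unavailable rather than failing the run.
#'
#' @param data Cohort data frame with columns `subject_id`, `side`,
#'   `volume_mm3`, `sex` (factor F/M), `age_years`, `anb_deg`,
#'   `divergence_deg`, `gonial_deg`.
#' @return An object of class `study_report` with elements `continuous`
#'   (per variable: `crude`, `adjusted`, `by_sex`), `categorical` (per
#'   axis: `crude`, `adjusted`), `summaries`, `n_subjects`, `n_condyles`.
#' @export
analyze_study <- function(data) {
  validate_cohort(data)
  need <- c("sex", "age_years", "anb_deg", "divergence_deg", "gonial_deg")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L) {
    stop(sprintf("cohort table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  data$sex <- factor(data$sex, levels = c("F", "M"))
  data <- add_pattern_labels(data)
  # reference levels per the study's summary table
  data$divergence_class <- stats::relevel(data$divergence_class, "normo")
  data$growth_class <- stats::relevel(data$growth_class, "normal")
  vars <- c("anb_deg", "divergence_deg", "gonial_deg")
  continuous <- lapply(stats::setNames(vars, vars), function(v) {
    by_sex <- lapply(stats::setNames(levels(data$sex), levels(data$sex)),
                     function(s) {
      sub <- data[data$sex == s, , drop = FALSE]
      if (nrow(sub) == 0L || length(unique(sub$subject_id)) < 3L) {
        structure(list(message = "fewer than 3 subjects in stratum"),
                  class = "ri_unavailable")
      } else {
        fit_or_note(sub, c(v, "age_years"), "volume_mm3", "subject_id")
      }
    })
    list(
      crude = fit_or_note(data, v, "volume_mm3", "subject_id"),
      adjusted = fit_or_note(data, c(v, "sex", "age_years"), "volume_mm3",
                             "subject_id"),
      by_sex = by_sex
    )
  })
  axes <- c("skeletal_class", "divergence_class", "growth_class")
  categorical <- lapply(stats::setNames(axes, axes), function(axis) {
    list(
      crude = fit_or_note(data, axis, "volume_mm3", "subject_id"),
      adjusted = fit_or_note(data, c(axis, "sex", "age_years"),
                             "volume_mm3", "subject_id")
    )
  })
  structure(
    list(continuous = continuous, categorical = categorical,
         summaries = group_summaries(data),
         n_subjects = length(unique(data$subject_id)),
         n_condyles = nrow(data)),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d condyles in %d subjects\n\n",
              x$n_condyles, x$n_subjects))
  cat("Group summaries (volume, mm^3):\n")
  print(transform(x$summaries,
                  median = round(median), mean = round(mean),
                  min = round(min), max = round(max), sd = round(sd)),
        row.names = FALSE)
  cat("\nContinuous variables (slope mm^3 per degree):\n")
  for (v in names(x$continuous)) {
    fits <- x$continuous[[v]]
    if (inherits(fits$crude, "ri_fit")) {
      row <- slope_of(fits$crude, v)
      cat(sprintf("  %-15s crude %7.2f (%.2f to %.2f), p = %.3g\n",
                  v, row$estimate, row$ci_lo, row$ci_hi, row$p_value))
    }
  }
  invisible(x)
}

#' Flatten a study report's regression battery to one table
#'
#' @param report A `study_report`.
#' @return Data frame with one row per fitted coefficient of interest:
#'   `variable`, `analysis`, `term`, `estimate`, `ci_lo`, `ci_hi`,
#'   `p_value`.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "study_report"))
  rows <- list()
  grab <- function(fit, variable, analysis, terms = NULL) {
    if (!inherits(fit, "ri_fit")) return(NULL)
    keep <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    if (!is.null(terms)) keep <- keep[keep$term %in% terms, ]
    if (nrow(keep) == 0L) return(NULL)
    cbind(variable = variable, analysis = analysis,
          keep[, c("term", "estimate", "ci_lo", "ci_hi", "p_value")])
  }
  for (v in names(report$continuous)) {
    fits <- report$continuous[[v]]
    rows[[length(rows) + 1L]] <- grab(fits$crude, v, "crude", v)
    rows[[length(rows) + 1L]] <- grab(fits$adjusted, v, "adjusted", v)
    for (s in names(fits$by_sex)) {
      rows[[length(rows) + 1L]] <-
        grab(fits$by_sex[[s]], v, paste0("stratified_", s), v)
    }
  }
  for (axis in names(report$categorical)) {
    fits <- report$categorical[[axis]]
    rows[[length(rows) + 1L]] <- grab(fits$crude, axis, "crude")
    rows[[length(rows) + 1L]] <- grab(fits$adjusted, axis, "adjusted")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
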