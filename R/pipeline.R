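#' Read a study configuration file
#'
#' YAML (or JSON) with fields: `subjects` — a list of entries with `id`,
#' `volume` (path), `landmarks` (path), `sex` (`F`/`M`), `age` (years) —
#' plus optional `hu_range` (default `[226, 3071]`) and `out_dir`. Relative
#' paths are resolved against the config file's directory.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A validated config list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file does not exist: %s", path), call. = FALSE)
  }
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  cfg$subjects <- lapply(cfg$subjects, function(s) {
    for (f in c("volume", "landmarks")) {
      if (!is.null(s[[f]]) && !grepl("^(/|[A-Za-z]:)", s[[f]])) {
        s[[f]] <- file.path(base, s[[f]])
      }
    }
    s
  })
  validate_study_config(cfg)
}

validate_study_config <- function(config) {
  if (is.null(config$subjects) || length(config$subjects) == 0L) {
    stop("config must list at least one subject", call. = FALSE)
  }
  if (is.null(config$hu_range)) config$hu_range <- c(226, 3071)
  hu <- as.numeric(config$hu_range)
  if (length(hu) != 2L || hu[1] > hu[2]) {
    stop("'hu_range' must be two numbers lo <= hi", call. = FALSE)
  }
  config$hu_range <- hu
  for (s in config$subjects) {
    for (f in c("id", "volume", "landmarks", "sex", "age")) {
      if (is.null(s[[f]])) {
        stop(sprintf("subject entry lacks field '%s'", f), call. = FALSE)
      }
    }
  }
  config
}

process_subject <- function(entry, hu_range) {
  vol <- read_volume(entry$volume)
  lm <- read_landmarks(entry$landmarks)
  meas <- measure_cephalometrics(lm)
  labels <- classify_pattern(meas$anb_deg, meas$divergence_deg,
                             meas$gonial_deg_mean)
  rows <- list()
  log <- list()
  for (side in c("R", "L")) {
    seg <- segment_condylar_head(vol, lm, side, hu_range[1], hu_range[2])
    rows[[side]] <- data.frame(
      subject_id = entry$id, side = side, volume_mm3 = seg$volume_mm3,
      sex = entry$sex, age_years = entry$age,
      anb_deg = meas$anb_deg, divergence_deg = meas$divergence_deg,
      gonial_deg = if (side == "R") meas$gonial_deg_R else meas$gonial_deg_L
    )
    log[[side]] <- list(
      side = side, n_voxels = seg$n_voxels, volume_mm3 = seg$volume_mm3,
      seed_point = seg$seed,
      cut_plane = list(p0 = seg$cut_plane$p0, normal = seg$cut_plane$normal),
      frankfurt = list(p0 = seg$frankfurt$p0, normal = seg$frankfurt$normal,
                       rmse = seg$frankfurt$rmse)
    )
  }
  list(rows = do.call(rbind, unname(rows)),
       measurements = cbind(subject_id = entry$id, meas, labels),
       log = list(subject_id = entry$id, sides = unname(log)))
}

#' Run the end-to-end condylar volumetry study
#'
#' For every configured subject: read the volume and landmarks, compute
#' the cephalometric measurements and pattern labels, segment both
#' condylar heads, and assemble the cohort table; then produce group
#' summaries and the full regression battery. Subjects whose processing
#' fails are quarantined with the failure reason; the run fails only when
#' every subject fails. The stage log records, per condyle, the exact cut
#' plane (point and normal), seed point and voxel count, so any volume can
#' be recomputed independently.
#'
#' @param config A config list (see [read_study_config()]) or a path to a
#'   config file.
#' @return An object of class `study_run`: `cohort` (data frame),
#'   `measurements`, `summaries`, `regressions` (a `study_report`, or a
#'   note when fewer than 3 subjects survive), `quarantine`, `log`.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  config <- validate_study_config(config)
  results <- list()
  quarantine <- list()
  for (entry in config$subjects) {
    res <- tryCatch(process_subject(entry, config$hu_range),
                    error = function(e) e)
    if (inherits(res, "error")) {
      quarantine[[length(quarantine) + 1L]] <-
        list(subject_id = entry$id, reason = conditionMessage(res))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  if (length(results) == 0L) {
    stop("all subjects failed; first reason: ",
         if (length(quarantine) > 0L) quarantine[[1]]$reason else "none",
         call. = FALSE)
  }
  cohort <- do.call(rbind, lapply(results, `[[`, "rows"))
  rownames(cohort) <- NULL
  measurements <- do.call(rbind, lapply(results, `[[`, "measurements"))
  rownames(measurements) <- NULL
  regressions <- if (length(unique(cohort$subject_id)) >= 3L) {
    tryCatch(analyze_study(cohort), error = function(e) {
      structure(list(message = conditionMessage(e)), class = "ri_unavailable")
    })
  } else {
    structure(list(message = "fewer than 3 subjects; regression skipped"),
              class = "ri_unavailable")
  }
  structure(
    list(cohort = cohort, measurements = measurements,
         summaries = group_summaries(cohort),
         regressions = regressions,
         quarantine = quarantine,
         log = lapply(results, `[[`, "log")),
    class = "study_run"
  )
}

#' @export
print.study_run <- function(x, ...) {
  cat(sprintf("<study_run> %d condyles from %d subject(s); %d quarantined\n",
              nrow(x$cohort), length(unique(x$cohort$subject_id)),
              length(x$quarantine)))
  invisible(x)
}

#' Write a study run to machine- and human-readable files
#'
#' Writes `cohort.csv`, `measurements.csv`, `summaries.csv`, a flattened
#' `regressions.csv` (when available) and a single `report.json` carrying
#' everything including the stage log. Output is deterministic: rerunning
#' on identical inputs produces byte-identical files.
#'
#' @param run A `study_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(run, dir) {
  stopifnot(inherits(run, "study_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(run$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(run$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  json <- list(
    cohort = run$cohort,
    summaries = run$summaries,
    quarantine = run$quarantine,
    log = run$log
  )
  if (inherits(run$regressions, "study_report")) {
    tab <- report_table(run$regressions)
    utils::write.csv(tab, file.path(dir, "regressions.csv"),
                     row.names = FALSE)
    json$regressions <- tab
  } else {
    json$regressions_note <- run$regressions$message
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Rater reliability study: inter- and intra-rater ICC(A,1)
#'
#' Mirrors the design in which several observers measure the condylar
#' volumes of a few subjects several times each: the inter-rater ICC is
#' computed on the subjects x raters matrix of per-rater session means,
#' and one intra-rater ICC per rater on that rater's subjects x sessions
#' matrix. All cells must be present.
#'
#' @param measurements Long data frame with columns `subject`, `rater`,
#'   `session`, `volume_mm3`.
#' @param conf_level Confidence level for all intervals.
#' @return An object of class `reliability_report`: `inter` (an
#'   `icc_result`), `intra` (named list of `icc_result` per rater),
#'   `n_subjects`, `n_raters`, `n_sessions`.
#' @export
reliability_study <- function(measurements, conf_level = 0.95) {
  need <- c("subject", "rater", "session", "volume_mm3")
  missing_cols <- setdiff(need, names(measurements))
  if (length(missing_cols) > 0L) {
    stop(sprintf("measurements lack column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  subj <- factor(measurements$subject)
  rater <- factor(measurements$rater)
  sess <- factor(measurements$session)
  full <- array(NA_real_,
                dim = c(nlevels(subj), nlevels(rater), nlevels(sess)))
  full[cbind(as.integer(subj), as.integer(rater), as.integer(sess))] <-
    measurements$volume_mm3
  if (anyNA(full)) {
    stop("missing cells: every subject x rater x session must be measured",
         call. = FALSE)
  }
  inter <- icc_a1(apply(full, c(1, 2), mean), conf_level)
  intra <- lapply(stats::setNames(seq_len(nlevels(rater)), levels(rater)),
                  function(j) icc_a1(full[, j, ], conf_level))
  structure(
    list(inter = inter, intra = intra,
         n_subjects = nlevels(subj), n_raters = nlevels(rater),
         n_sessions = nlevels(sess)),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf(
    "Reliability: %d subjects, %d raters, %d sessions\n  inter-rater ",
    x$n_subjects, x$n_raters, x$n_sessions))
  print(x$inter)
  for (r in names(x$intra)) {
    cat(sprintf("  intra-rater %s ", r))
    print(x$intra[[r]])
  }
  invisible(x)
}
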