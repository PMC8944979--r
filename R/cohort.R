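#' Specification of a simulated study cohort
#'
#' Defines the generative model for a two-condyles-per-subject cohort:
#' per subject draw sex, age and the three cephalometric covariates, a
#' subject effect `b_i ~ N(0, tau^2)`, and per condyle
#' `volume = intercept + sex_effect * [male] + sum slope * (covariate -
#' center) + b_i + e`, `e ~ N(0, sigma^2)`.
#'
#' Defaults encode the study conditions this package emulates: 49 female
#' and 24 male subjects; female mean volume 701 mm^3 with a +141 mm^3 male
#' effect; covariates centered on the clinical norms (ANB 2, divergence
#' 41, gonial 120) with spreads chosen so the expected class occupancies
#' match the reported group sizes (SDs 5.4, 4.0 and 6.0 degrees); negative
#' divergence and gonial slopes sized so the expected pattern-group means
#' reproduce the reported group gradients (-16 and -16.5 mm^3 per degree);
#' a weak ANB slope (-5); and variance components tau = 180, sigma = 120
#' mm^3 (total within-group SD ~ 250 mm^3 once covariate variance is
#' added). Age is N(30, 12) truncated at 18 with no age effect.
#'
#' @param n_female,n_male Numbers of subjects.
#' @param intercept Female mean volume at covariate centers (mm^3).
#' @param sex_effect Additional male mean volume (mm^3).
#' @param slopes Named numeric: mm^3 per degree for `anb_deg`,
#'   `divergence_deg`, `gonial_deg`.
#' @param centers,sds Named numeric: covariate means and SDs (degrees).
#' @param tau Between-subject SD (mm^3).
#' @param sigma Within-subject (per-condyle) SD (mm^3).
#' @param age_mean,age_sd,age_min Age distribution (years; normal,
#'   truncated below).
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_female = 49, n_male = 24, intercept = 701,
                        sex_effect = 141,
                        slopes = c(anb_deg = -5, divergence_deg = -16,
                                   gonial_deg = -16.5),
                        centers = c(anb_deg = 2, divergence_deg = 41,
                                    gonial_deg = 120),
                        sds = c(anb_deg = 5.4, divergence_deg = 4,
                                gonial_deg = 6),
                        tau = 180, sigma = 120,
                        age_mean = 30, age_sd = 12, age_min = 18,
                        seed = NULL) {
  if (n_female + n_male <= 0) stop("cohort must be non-empty", call. = FALSE)
  if (n_female < 0 || n_male < 0) {
    stop("subject counts must be non-negative", call. = FALSE)
  }
  covs <- c("anb_deg", "divergence_deg", "gonial_deg")
  for (nm in list(slopes, centers, sds)) {
    if (!all(covs %in% names(nm))) {
      stop(sprintf("slopes/centers/sds must be named with: %s",
                   paste(covs, collapse = ", ")), call. = FALSE)
    }
  }
  if (any(sds < 0) || tau < 0 || sigma < 0 || age_sd < 0) {
    stop("all SDs must be >= 0", call. = FALSE)
  }
  structure(
    list(n_female = n_female, n_male = n_male, intercept = intercept,
         sex_effect = sex_effect, slopes = slopes[covs],
         centers = centers[covs], sds = sds[covs], tau = tau, sigma = sigma,
         age_mean = age_mean, age_sd = age_sd, age_min = age_min,
         seed = seed),
    class = "cohort_spec"
  )
}

#' Simulate a two-condyles-per-subject cohort table
#'
#' Deterministic under a fixed `spec$seed`. Volumes are floored at 1 mm^3
#' (the generative normal model has a small negative tail; cohort tables
#' require positive volumes).
#'
#' @param spec A `cohort_spec`.
#' @return Cohort data frame: `subject_id`, `side`, `volume_mm3`, `sex`,
#'   `age_years`, `anb_deg`, `divergence_deg`, `gonial_deg`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_female + spec$n_male
  with_seed(spec$seed, {
    sex <- factor(rep(c("F", "M"), c(spec$n_female, spec$n_male)),
                  levels = c("F", "M"))
    age <- pmax(spec$age_min,
                stats::rnorm(n, spec$age_mean, spec$age_sd))
    covs <- sapply(names(spec$centers), function(v) {
      stats::rnorm(n, spec$centers[[v]], spec$sds[[v]])
    })
    b <- stats::rnorm(n, 0, spec$tau)
    mu <- spec$intercept + spec$sex_effect * (sex == "M") +
      as.vector((covs - rep(spec$centers, each = n)) %*% spec$slopes) + b
    eps <- matrix(stats::rnorm(2 * n, 0, spec$sigma), nrow = n)
    vol <- cbind(mu + eps[, 1], mu + eps[, 2])
    data.frame(
      subject_id = rep(sprintf("S%03d", seq_len(n)), each = 2L),
      side = rep(c("R", "L"), times = n),
      volume_mm3 = pmax(1, as.vector(t(vol))),
      sex = rep(sex, each = 2L),
      age_years = rep(age, each = 2L),
      anb_deg = rep(covs[, "anb_deg"], each = 2L),
      divergence_deg = rep(covs[, "divergence_deg"], each = 2L),
      gonial_deg = rep(covs[, "gonial_deg"], each = 2L)
    )
  })
}
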