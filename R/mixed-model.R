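#' Validate a cohort table
#'
#' A cohort table is long format, one row per condyle: at most two rows per
#' subject, distinct sides within a subject, strictly positive volumes.
#'
#' @param data Data frame with at least `subject_id`, `side`, `volume_mm3`.
#' @return `data`, invisibly, after validation.
#' @export
validate_cohort <- function(data) {
  need <- c("subject_id", "side", "volume_mm3")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0L) {
    stop(sprintf("cohort table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(data) == 0L) stop("cohort table is empty", call. = FALSE)
  tab <- table(data$subject_id)
  if (any(tab > 2L)) {
    stop(sprintf("subject(s) with more than two condyles: %s",
                 paste(names(tab)[tab > 2L], collapse = ", ")), call. = FALSE)
  }
  dup <- duplicated(data[, c("subject_id", "side")])
  if (any(dup)) {
    stop(sprintf("duplicated side within subject(s): %s",
                 paste(unique(data$subject_id[dup]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.finite(data$volume_mm3)) || any(data$volume_mm3 <= 0)) {
    stop("volumes must be finite and strictly positive", call. = FALSE)
  }
  invisible(data)
}

# Profiled REML pieces for the random-intercept model, as functions of the
# variance ratio gamma = tau^2 / sigma^2. For V0 = I + gamma Z Z' with a
# single grouping factor, each subject block inverts in closed form:
# (I + gamma J_m)^{-1} = I - gamma/(1 + m gamma) J_m, det = 1 + m gamma.
ri_profile <- function(gamma, pre) {
  cg <- gamma / (1 + pre$m * gamma)
  A <- pre$XtX - crossprod(pre$S1 * sqrt(cg))
  b <- pre$Xty - as.vector(crossprod(pre$S1, cg * pre$Sy))
  beta <- solve(A, b)
  rss <- pre$yty - sum(cg * pre$Sy^2) - sum(b * beta)
  rss <- max(rss, 1e-300)
  sigma2 <- rss / (pre$n - pre$p)
  logdetV0 <- sum(log1p(pre$m * gamma))
  cholA <- chol(A)
  logdetA <- 2 * sum(log(diag(cholA)))
  # restricted log-likelihood (full constant included)
  ll <- -0.5 * ((pre$n - pre$p) * (log(2 * pi * sigma2) + 1) +
                  logdetV0 + logdetA)
  list(ll = ll, beta = beta, sigma2 = sigma2, A = A)
}

#' Random-intercept linear regression by REML
#'
#' Fits the two-level model `y_ij = x_ij' beta + b_i + e_ij` with
#' `b_i ~ N(0, tau^2)` per subject and `e_ij ~ N(0, sigma^2)`, the standard
#' structure for two correlated condyles per subject. Variance components
#' are estimated by restricted maximum likelihood, profiling out `beta` and
#' `sigma^2` and optimizing the one remaining parameter on the
#' log-variance-ratio scale (tolerance 1e-8 on the restricted
#' log-likelihood; `tau^2` floored at zero by comparing against the
#' boundary fit, which is ordinary least squares). Confidence intervals and
#' p-values are Wald, from the normal approximation — the convention of the
#' mixed-model commands in the major commercial statistics packages.
#'
#' @param data Cohort data frame (see [validate_cohort()]).
#' @param outcome Name of the outcome column (default `"volume_mm3"`).
#' @param covariates Character vector of covariate column names; factors
#'   are expanded to treatment-coded indicators (sex enters as an indicator
#'   with female = 0, male = 1 when coded as a factor with levels F, M).
#' @param subject Name of the grouping column (default `"subject_id"`).
#' @param conf_level Wald confidence level (default 0.95).
#' @return An object of class `ri_fit`: `coefficients` data frame (term,
#'   estimate, se, ci_lo, ci_hi, p_value), `tau2`, `sigma2`, `logLik_reml`,
#'   `n_subjects`, `n_condyles`.
#' @export
fit_random_intercept <- function(data, outcome = "volume_mm3", covariates,
                                 subject = "subject_id", conf_level = 0.95) {
  cols <- c(outcome, covariates, subject)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    stop(sprintf("data lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  y <- as.numeric(data[[outcome]])
  id <- factor(data[[subject]])
  if (anyNA(y) || any(!is.finite(y))) {
    stop("outcome must be finite", call. = FALSE)
  }
  if (nlevels(id) < 3L) {
    stop("need at least 3 subjects to fit a random-intercept model",
         call. = FALSE)
  }
  X <- stats::model.matrix(~., data = data[, covariates, drop = FALSE])
  n <- length(y)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  pre <- list(
    n = n, p = p,
    XtX = crossprod(X), Xty = as.vector(crossprod(X, y)), yty = sum(y^2),
    S1 = rowsum(X, id), Sy = as.vector(rowsum(y, id)),
    m = as.vector(table(id))
  )
  # deterministic initialization/bracket: gamma = tau^2/sigma^2 in
  # [e^-16, e^10], plus the exact boundary gamma = 0 (OLS)
  opt <- stats::optimize(function(t) ri_profile(exp(t), pre)$ll,
                         interval = c(-16, 10), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  at_boundary <- ri_profile(0, pre)
  if (at_boundary$ll >= opt$objective - 1e-8) {
    gamma <- 0
    sol <- at_boundary
  } else {
    gamma <- exp(opt$maximum)
    sol <- ri_profile(gamma, pre)
  }
  vc <- sol$sigma2 * solve(sol$A)
  se <- sqrt(diag(vc))
  z <- sol$beta / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(
    term = colnames(X),
    estimate = as.numeric(sol$beta),
    se = se,
    ci_lo = as.numeric(sol$beta) - q * se,
    ci_hi = as.numeric(sol$beta) + q * se,
    p_value = 2 * stats::pnorm(-abs(z)),
    row.names = NULL
  )
  structure(
    list(coefficients = coefs, tau2 = gamma * sol$sigma2,
         sigma2 = sol$sigma2, gamma = gamma, logLik_reml = sol$ll,
         conf_level = conf_level, outcome = outcome,
         covariates = covariates,
         n_subjects = nlevels(id), n_condyles = n),
    class = "ri_fit"
  )
}

#' Extract one covariate's row from a random-intercept fit
#'
#' @param fit An `ri_fit`.
#' @param term Coefficient name (as expanded in the design matrix).
#' @return One-row data frame (term, estimate, se, ci_lo, ci_hi, p_value).
#' @export
slope_of <- function(fit, term) {
  stopifnot(inherits(fit, "ri_fit"))
  row <- fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop(sprintf("no coefficient named '%s'", term), call. = FALSE)
  }
  row
}

#' @export
print.ri_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Random-intercept linear model (REML): %s ~ %s\n",
    x$outcome, paste(x$covariates, collapse = " + ")))
  cat(sprintf("  %d condyles in %d subjects; tau^2 = %.4g, sigma^2 = %.4g\n",
              x$n_condyles, x$n_subjects, x$tau2, x$sigma2))
  print(cbind(
    x$coefficients[, "term", drop = FALSE],
    round(x$coefficients[, c("estimate", "se", "ci_lo", "ci_hi")], digits),
    p_value = signif(x$coefficients$p_value, 2)
  ), row.names = FALSE)
  invisible(x)
}
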