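#' Intraclass correlation ICC(A,1): two-way, absolute agreement, single
#' measurement
#'
#' McGraw-Wong ICC(A,1) from the two-way (subjects x raters) mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, the form SPSS
#' labels "two-way mixed, absolute agreement, single measures". The
#' confidence interval is the F-based method with Satterthwaite denominator
#' degrees of freedom.
#'
#' @param ratings Numeric n x k matrix: n subjects (rows) rated by k raters
#'   or sessions (columns). No missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `icc_result`: `icc`, `ci` (lower, upper),
#'   `ms` (rows, columns, error), `n_subjects`, `k_raters`.
#' @export
icc_a1 <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2L || k < 2L) {
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  }
  if (anyNA(ratings) || any(!is.finite(ratings))) {
    stop("ratings must be complete (no missing cells)", call. = FALSE)
  }
  grand <- mean(ratings)
  row_means <- rowMeans(ratings)
  col_means <- colMeans(ratings)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level
  if (mse <= 0 && msc <= 0) {
    # degenerate perfect agreement
    ci <- c(1, 1)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_u <- stats::qf(1 - alpha / 2, n - 1, v)
    lower <- n * (msr - f_u * mse) /
      (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
    f_l <- stats::qf(1 - alpha / 2, v, n - 1)
    upper <- n * (f_l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_l * msr)
    ci <- c(lower, upper)
  }
  structure(
    list(icc = icc, ci = ci, conf_level = conf_level,
         ms = c(rows = msr, columns = msc, error = mse),
         n_subjects = n, k_raters = k),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(A,1) = %.4f (%.0f%% CI %.4f to %.4f); %d subjects x %d raters\n",
    x$icc, 100 * x$conf_level, x$ci[1], x$ci[2], x$n_subjects, x$k_raters))
  invisible(x)
}
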