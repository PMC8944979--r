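#' Skeletal pattern classification from the three cephalometric angles
#'
#' Maps angle values to the categorical groups of the study design. The
#' central groups are closed intervals around the clinical norms
#' (ANB 2 +/- 2 deg, divergence 41 +/- 1 deg, total gonial 120 +/- 5 deg);
#' boundary values are assigned to the central class:
#' \itemize{
#'   \item skeletal class: I iff 0 <= ANB <= 4, II iff ANB > 4,
#'     III iff ANB < 0;
#'   \item divergence: normo iff 40 <= d <= 42, hypo below, hyper above;
#'   \item growth: normal iff 115 <= g <= 125, horizontal below
#'     (decreased gonial angle), post-rotation above (increased).
#' }
#'
#' @param anb_deg,divergence_deg,gonial_deg Numeric vectors (degrees),
#'   recycled to common length; `gonial_deg` is conventionally the mean of
#'   the two sides.
#' @return Data frame with factor columns `skeletal_class` (levels I, II,
#'   III), `divergence_class` (hypo, normo, hyper) and `growth_class`
#'   (horizontal, normal, post_rotation).
#' @export
classify_pattern <- function(anb_deg, divergence_deg, gonial_deg) {
  n <- max(length(anb_deg), length(divergence_deg), length(gonial_deg))
  anb <- rep_len(as.numeric(anb_deg), n)
  div <- rep_len(as.numeric(divergence_deg), n)
  gon <- rep_len(as.numeric(gonial_deg), n)
  if (anyNA(anb) || anyNA(div) || anyNA(gon) ||
      any(!is.finite(c(anb, div, gon)))) {
    stop("classification inputs must be finite (no NA/NaN)", call. = FALSE)
  }
  skeletal <- ifelse(anb < 0, "III", ifelse(anb > 4, "II", "I"))
  divergence <- ifelse(div < 40, "hypo", ifelse(div > 42, "hyper", "normo"))
  growth <- ifelse(gon < 115, "horizontal",
                   ifelse(gon > 125, "post_rotation", "normal"))
  data.frame(
    skeletal_class = factor(skeletal, levels = c("I", "II", "III")),
    divergence_class = factor(divergence, levels = c("hypo", "normo", "hyper")),
    growth_class = factor(growth,
                          levels = c("horizontal", "normal", "post_rotation"))
  )
}

#' Append pattern labels to a cohort table
#'
#' @param data Cohort data frame with columns `anb_deg`, `divergence_deg`
#'   and `gonial_deg`.
#' @return `data` with the three label columns of [classify_pattern()]
#'   appended (existing label columns are recomputed).
#' @export
add_pattern_labels <- function(data) {
  need <- c("anb_deg", "divergence_deg", "gonial_deg")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0L) {
    stop(sprintf("cohort table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  labels <- classify_pattern(data$anb_deg, data$divergence_deg,
                             data$gonial_deg)
  data[names(labels)] <- labels
  data
}
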