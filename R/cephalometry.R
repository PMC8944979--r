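angle_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9) {
    stop("zero-length direction in angle computation", call. = FALSE)
  }
  rad2deg(acos(max(-1, min(1, sum(u * v) / (nu * nv)))))
}

anterior_axis <- function(lm) {
  # unit anterior direction: N -> midpoint(Ans, Pns), component orthogonal
  # to the Frankfurt normal; +x when the construction is unavailable
  fallback <- c(1, 0, 0)
  if (!has_landmarks(lm, c("N", "Ans", "Pns"))) return(fallback)
  m <- (lm_point(lm, "Ans") + lm_point(lm, "Pns")) / 2 - lm_point(lm, "N")
  if (has_landmarks(lm, c("Po_R", "Po_L", "Or_R", "Or_L"))) {
    n <- frankfurt_plane(lm)$normal
    m <- m - sum(m * n) * n
  }
  if (sqrt(sum(m^2)) < 1e-9) return(fallback)
  unit(m)
}

#' ANB angle (signed degrees)
#'
#' Unsigned angle at nasion between the rays N->A and N->B, signed by the
#' antero-posterior ordering of A versus B: positive when A projects
#' anterior to B on the anterior axis (so skeletal Class III values come
#' out negative, as on a lateral cephalogram). The anterior axis is the
#' component of N->midpoint(Ans, Pns) orthogonal to the Frankfurt normal,
#' falling back to +x when those landmarks are absent or degenerate.
#'
#' @param lm A `landmark_set` containing A, B and N (Ans, Pns, Po, Or used
#'   for the sign when present).
#' @return Signed ANB in degrees.
#' @export
anb_angle <- function(lm) {
  pts <- require_landmarks(lm, c("A", "B", "N"))
  u <- pts["A", ] - pts["N", ]
  v <- pts["B", ] - pts["N", ]
  if (sqrt(sum(u^2)) < 1e-9 || sqrt(sum(v^2)) < 1e-9) {
    stop("A or B coincides with N", call. = FALSE)
  }
  ang <- angle_deg(u, v)
  ax <- anterior_axis(lm)
  s <- if (sum((pts["A", ] - pts["B", ]) * ax) >= 0) 1 else -1
  s * ang
}

#' Intermaxillary divergence angle (degrees, folded to [0, 90])
#'
#' Angle between the maxillary line Ans->Pns and the mandibular line
#' midpoint(Go_R, Go_L)->Me, computed as `acos(|u.v|)` so line (not ray)
#' orientation cannot push it past 90 degrees.
#'
#' @param lm A `landmark_set` containing Ans, Pns, Go_R, Go_L and Me.
#' @return Divergence in degrees, in `[0, 90]`.
#' @export
divergence_angle <- function(lm) {
  pts <- require_landmarks(lm, c("Ans", "Pns", "Go_R", "Go_L", "Me"))
  u <- pts["Pns", ] - pts["Ans", ]
  go_mid <- (pts["Go_R", ] + pts["Go_L", ]) / 2
  v <- pts["Me", ] - go_mid
  if (sqrt(sum(u^2)) < 1e-9 || sqrt(sum(v^2)) < 1e-9) {
    stop("zero-length maxillary or mandibular direction", call. = FALSE)
  }
  rad2deg(acos(min(1, abs(sum(unit(u) * unit(v))))))
}

#' Total gonial angle of one side (degrees, unfolded)
#'
#' Unsigned angle at gonion between the ramus ray Go->Cd and the body ray
#' Go->Me of the same side. Obtuse values are preserved (a 120-degree
#' construction reads 120, never 60).
#'
#' @param lm A `landmark_set` containing `Go_<side>`, `Cd_<side>` and Me.
#' @param side `"R"` or `"L"`.
#' @return Gonial angle in degrees, in `[0, 180]`.
#' @export
gonial_angle <- function(lm, side = c("R", "L")) {
  side <- match.arg(side)
  pts <- require_landmarks(lm, c(paste0("Go_", side), paste0("Cd_", side), "Me"))
  go <- pts[paste0("Go_", side), ]
  u <- pts[paste0("Cd_", side), ] - go
  v <- pts["Me", ] - go
  if (sqrt(sum(u^2)) < 1e-9 || sqrt(sum(v^2)) < 1e-9) {
    stop(sprintf("coincident landmarks at Go_%s", side), call. = FALSE)
  }
  angle_deg(u, v)
}

#' All cephalometric measurements used by the study
#'
#' @param lm A `landmark_set` with the full required vocabulary
#'   (A, B, N, Ans, Pns, Me, Go and Cd bilaterally; Po/Or recommended for
#'   the ANB sign convention).
#' @return One-row data frame with columns `anb_deg`, `divergence_deg`,
#'   `gonial_deg_R`, `gonial_deg_L` and `gonial_deg_mean`.
#' @export
measure_cephalometrics <- function(lm) {
  gr <- gonial_angle(lm, "R")
  gl <- gonial_angle(lm, "L")
  data.frame(
    anb_deg = anb_angle(lm),
    divergence_deg = divergence_angle(lm),
    gonial_deg_R = gr,
    gonial_deg_L = gl,
    gonial_deg_mean = (gr + gl) / 2
  )
}
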