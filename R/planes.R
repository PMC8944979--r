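#' Oriented plane in world coordinates
#'
#' Point-normal representation; the normal is stored at unit length and the
#' sign of `signed_distance()` follows it. Constructions that carry an
#' orientation contract ([frankfurt_plane()], [condylar_cut_plane()])
#' document which side is positive.
#'
#' @param p0 Length-3 point on the plane (mm).
#' @param normal Length-3 normal vector (any nonzero length).
#' @return An object of class `plane`.
#' @export
plane <- function(p0, normal) {
  p0 <- as.numeric(p0)
  if (length(p0) != 3L || any(!is.finite(p0))) {
    stop("'p0' must be a finite length-3 point", call. = FALSE)
  }
  structure(list(p0 = p0, normal = unit(as.numeric(normal))),
            class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("<plane> p0 = (%.3f, %.3f, %.3f), n = (%.4f, %.4f, %.4f)\n",
              x$p0[1], x$p0[2], x$p0[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Signed distance from points to a plane
#'
#' @param pl A `plane`.
#' @param x Length-3 point or n x 3 matrix of world points (mm).
#' @return Signed distances (mm); positive on the side the normal points to.
#' @export
signed_distance <- function(pl, x) {
  stopifnot(inherits(pl, "plane"))
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 3L)
  as.vector(sweep(x, 2L, pl$p0) %*% pl$normal)
}

flip_plane <- function(pl) plane(pl$p0, -pl$normal)

#' Total-least-squares plane through three or more points
#'
#' Minimizes the sum of squared orthogonal distances (the SVD solution
#' through the centroid), which reduces to exact interpolation whenever the
#' points are coplanar, and is equivariant under rigid motion.
#'
#' @param points n x 3 matrix (n >= 3) of world points; row names are used
#'   in error messages.
#' @return A `plane`. The normal's sign is unspecified here; orientation
#'   contracts are applied by the callers.
#' @export
fit_plane <- function(points) {
  points <- unclass(as.matrix(points))
  if (nrow(points) < 3L || ncol(points) != 3L) {
    stop("need at least 3 points with 3 coordinates", call. = FALSE)
  }
  ctr <- colMeans(points)
  centered <- sweep(points, 2L, ctr)
  sv <- svd(centered)
  # collinear (or coincident) points leave the second singular value ~ 0
  scale_ref <- max(sv$d[1], 1e-8)
  if (sv$d[2] / scale_ref < 1e-9) {
    nm <- rownames(points)
    who <- if (is.null(nm)) "the supplied points" else paste(nm, collapse = ", ")
    stop(sprintf("degenerate (collinear) plane fit from: %s", who),
         call. = FALSE)
  }
  normal <- sv$v[, 3L]
  res <- plane(ctr, normal)
  res$rmse <- sqrt(mean(signed_distance(res, points)^2))
  res$max_residual <- max(abs(signed_distance(res, points)))
  res
}

#' Frankfurt horizontal plane from porion and orbital landmarks
#'
#' Total-least-squares plane through Po_R, Po_L, Or_R and Or_L (four points
#' are generally not exactly coplanar). The normal is oriented so that
#' menton (Me), when present, lies on the negative side — the Frankfurt
#' plane sits above the chin. Without Me, the normal's largest-magnitude
#' component is made positive.
#'
#' @param lm A `landmark_set` containing Po_R, Po_L, Or_R, Or_L
#'   (Me recommended for orientation).
#' @return A `plane` with the orientation contract above.
#' @export
frankfurt_plane <- function(lm) {
  pts <- require_landmarks(lm, c("Po_R", "Po_L", "Or_R", "Or_L"))
  pl <- fit_plane(pts)
  if (has_landmarks(lm, "Me")) {
    if (signed_distance(pl, lm_point(lm, "Me")) > 0) pl <- flip_plane(pl)
  } else {
    i <- which.max(abs(pl$normal))
    if (pl$normal[i] < 0) pl <- flip_plane(pl)
  }
  pl
}

#' Condylar cut plane through the pterygoid fovea
#'
#' The plane through FP of the requested side, parallel to the Frankfurt
#' plane. The normal is oriented so that the condylar head side is
#' positive: condylion (Cd) of the same side, when present, has
#' non-negative signed distance.
#'
#' @param lm A `landmark_set` containing `FP_<side>` (and ideally
#'   `Cd_<side>`).
#' @param side `"R"` or `"L"`.
#' @param frankfurt A `plane`, usually from [frankfurt_plane()].
#' @return A `plane` whose positive side contains the condylar head.
#' @export
condylar_cut_plane <- function(lm, side = c("R", "L"), frankfurt) {
  side <- match.arg(side)
  stopifnot(inherits(frankfurt, "plane"))
  fp <- lm_point(lm, paste0("FP_", side))
  pl <- plane(fp, frankfurt$normal)
  cd_name <- paste0("Cd_", side)
  if (has_landmarks(lm, cd_name)) {
    if (signed_distance(pl, lm_point(lm, cd_name)) < 0) pl <- flip_plane(pl)
  }
  pl
}
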