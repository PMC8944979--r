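#' Bone-density threshold mask
#'
#' Voxel true iff its HU value lies in the closed interval `[lo, hi]`. The
#' clinical default range for bone is 226-3071 HU.
#'
#' @param vol A `voxel_volume`.
#' @param lo,hi Inclusive HU bounds, `lo <= hi`.
#' @return Logical 3D array aligned with `vol$values`.
#' @export
threshold_mask <- function(vol, lo = 226, hi = 3071) {
  stopifnot(inherits(vol, "voxel_volume"))
  stop_if_not_scalar_number(lo, "lo")
  stop_if_not_scalar_number(hi, "hi")
  if (lo > hi) stop("'lo' must not exceed 'hi'", call. = FALSE)
  vol$values >= lo & vol$values <= hi
}

# signed distance of every voxel center to a plane, as a separable sum:
# n . (origin + M (ijk - 1) - p0) with M = orientation %*% diag(spacing)
plane_distance_grid <- function(vol, pl) {
  d <- dim(vol$values)
  M <- vol$orientation %*% diag(vol$spacing)
  a <- as.vector(pl$normal %*% M)
  base <- sum(pl$normal * (vol$origin - pl$p0))
  di <- (seq_len(d[1]) - 1) * a[1]
  dj <- (seq_len(d[2]) - 1) * a[2]
  dk <- (seq_len(d[3]) - 1) * a[3]
  outer(outer(di + base, dj, `+`), dk, `+`)
}

neighbor_offsets_26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

#' Connected component containing a seed point
#'
#' Returns the 26-connected component of the mask that contains the voxel
#' nearest the world-coordinate seed. If the seed's own voxel is false, the
#' nearest true voxel within `radius` mm is used instead; no true voxel
#' within `radius` is an error. The radius guards against silently grabbing
#' distant structures (e.g. the skull base) through a misplaced seed.
#'
#' @param mask Logical 3D array (from [threshold_mask()]).
#' @param seed Length-3 world point (mm).
#' @param vol The `voxel_volume` the mask is aligned with.
#' @param radius Seed search radius in mm (default 25).
#' @return Logical array of the same shape: the selected component.
#' @export
seeded_component <- function(mask, seed, vol, radius = 25) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$values)
  if (!is.logical(mask) || !identical(dim(mask), d)) {
    stop("'mask' must be a logical array matching the volume", call. = FALSE)
  }
  if (!any(mask)) {
    stop(sprintf("no foreground voxel within %.0f mm of the seed", radius),
         call. = FALSE)
  }
  true_lin <- which(mask)
  true_ijk <- arrayInd(true_lin, d)
  w <- index_to_world(vol, true_ijk)
  dist2 <- rowSums(sweep(w, 2L, as.numeric(seed))^2)
  i_min <- which.min(dist2)
  if (dist2[i_min] > radius^2) {
    stop(sprintf("no foreground voxel within %.0f mm of the seed", radius),
         call. = FALSE)
  }
  # breadth-first flood fill, 26-connectivity, vectorized over the frontier
  visited <- array(FALSE, dim = d)
  start <- true_ijk[i_min, , drop = FALSE]
  visited[start] <- TRUE
  frontier <- start
  off <- neighbor_offsets_26
  n_off <- nrow(off)
  while (nrow(frontier) > 0L) {
    cand <- frontier[rep(seq_len(nrow(frontier)), each = n_off), , drop = FALSE] +
      off[rep(seq_len(n_off), times = nrow(frontier)), , drop = FALSE]
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
      cand[, 2] >= 1 & cand[, 2] <= d[2] &
      cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    lin <- (cand[, 3] - 1) * d[1] * d[2] + (cand[, 2] - 1) * d[1] + cand[, 1]
    keep <- !duplicated(lin)
    cand <- cand[keep, , drop = FALSE]
    lin <- lin[keep]
    grow <- mask[lin] & !visited[lin]
    visited[lin[grow]] <- TRUE
    frontier <- cand[grow, , drop = FALSE]
  }
  visited
}

#' Clip a mask to the positive side of a plane
#'
#' Keeps voxels whose centers have non-negative signed distance from the
#' plane; centers exactly on the plane are kept (evaluated with a 1e-9 mm
#' slack against floating-point ties).
#'
#' @param mask Logical 3D array.
#' @param pl A `plane` oriented head-side positive
#'   (the [condylar_cut_plane()] contract).
#' @param vol The `voxel_volume` the mask is aligned with.
#' @return Logical array: the clipped mask.
#' @export
clip_above_plane <- function(mask, pl, vol) {
  stopifnot(inherits(pl, "plane"), inherits(vol, "voxel_volume"))
  if (!is.logical(mask) || !identical(dim(mask), dim(vol$values))) {
    stop("'mask' must be a logical array matching the volume", call. = FALSE)
  }
  mask & (plane_distance_grid(vol, pl) >= -1e-9)
}

#' Segment the condylar head and measure its volume
#'
#' Reproduces the protocol: bone threshold (closed HU interval), isolation
#' of the condyle as the connected component around the condylion seed, and
#' separation of the head from the neck by the cut plane through the
#' pterygoid fovea parallel to the Frankfurt plane. Volume is voxel-center
#' counting times the voxel volume (no partial-volume weighting).
#'
#' @param vol A `voxel_volume` (HU).
#' @param lm A `landmark_set` with Po_R/Po_L/Or_R/Or_L and `FP_<side>`
#'   (`Cd_<side>` recommended; used as the component seed).
#' @param side `"R"` or `"L"`.
#' @param hu_lo,hu_hi Inclusive HU bounds (default 226 and 3071).
#' @return An object of class `condyle_segmentation`: list with `side`,
#'   `mask`, `n_voxels`, `volume_mm3`, `cut_plane`, `frankfurt`, `hu_range`
#'   and `seed`.
#' @export
segment_condylar_head <- function(vol, lm, side = c("R", "L"),
                                  hu_lo = 226, hu_hi = 3071) {
  side <- match.arg(side)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  fp <- stage("frankfurt_plane", frankfurt_plane(lm))
  cut <- stage("condylar_cut_plane", condylar_cut_plane(lm, side, fp))
  mask <- stage("threshold_mask", threshold_mask(vol, hu_lo, hu_hi))
  cd_name <- paste0("Cd_", side)
  seed <- if (has_landmarks(lm, cd_name)) {
    lm_point(lm, cd_name)
  } else {
    lm_point(lm, paste0("FP_", side)) + 10 * cut$normal
  }
  comp <- stage("seeded_component", seeded_component(mask, seed, vol))
  head <- stage("clip_above_plane", clip_above_plane(comp, cut, vol))
  n_vox <- sum(head)
  structure(
    list(side = side, mask = head, n_voxels = n_vox,
         volume_mm3 = n_vox * voxel_size_mm3(vol),
         cut_plane = cut, frankfurt = fp,
         hu_range = c(hu_lo, hu_hi), seed = as.numeric(seed)),
    class = "condyle_segmentation"
  )
}

#' @export
print.condyle_segmentation <- function(x, ...) {
  cat(sprintf(
    "<condyle_segmentation> side %s: %d voxels, %.1f mm^3 (HU %g-%g)\n",
    x$side, x$n_voxels, x$volume_mm3, x$hu_range[1], x$hu_range[2]))
  cat(sprintf("  cut plane p0 (%.2f, %.2f, %.2f), n (%.3f, %.3f, %.3f)\n",
              x$cut_plane$p0[1], x$cut_plane$p0[2], x$cut_plane$p0[3],
              x$cut_plane$normal[1], x$cut_plane$normal[2],
              x$cut_plane$normal[3]))
  invisible(x)
}
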