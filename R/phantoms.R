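#' Analytic volume of an ellipsoid cap
#'
#' Volume of `x^2/a^2 + y^2/b^2 + z^2/c^2 <= 1` above the horizontal cut
#' `z = h` (h measured from the center, `h` in `[-c, c]`):
#' `pi * a * b * (2c/3 - h + h^3 / (3 c^2))`. At `h = -c` this is the full
#' ellipsoid `4/3 pi a b c`; at `h = 0`, exactly half.
#'
#' @param a,b,c Semi-axes (mm), > 0.
#' @param h Signed cut height relative to the center, along the cut normal.
#' @return Cap volume in mm^3.
#' @export
ellipsoid_cap_volume <- function(a, b, c, h) {
  if (any(c(a, b, c) <= 0)) stop("semi-axes must be > 0", call. = FALSE)
  if (any(h < -c - 1e-9) || any(h > c + 1e-9)) {
    stop("'h' must lie in [-c, c]", call. = FALSE)
  }
  pi * a * b * (2 * c / 3 - h + h^3 / (3 * c^2))
}

#' Specification of a condyle-like voxel phantom
#'
#' An ellipsoidal "head" (the condylar head, elliptical in adults) on a
#' cylindrical "neck", rendered at bone HU on a soft-tissue/air background
#' at CBCT-like voxel geometry. The cut height `cut_height_mm` is the
#' signed height of the head/neck junction above the head center along the
#' cut normal; the neck is attached strictly below that plane so the
#' analytic cap volume is the exact expected head volume.
#'
#' @param a,b,c Head semi-axes (mm).
#' @param center Head center, world mm.
#' @param cut_height_mm Cut height `h` relative to the center, in
#'   `[-c, c]`; default `-c/2`.
#' @param neck_radius,neck_length Neck cylinder geometry (mm).
#' @param bone_hu HU of bone voxels (default 1200; must lie inside the
#'   segmentation range 226-3071).
#' @param background_hu HU elsewhere (default 0).
#' @param noise_sd Additive Gaussian HU noise SD (default 0).
#' @param spacing Voxel spacing (mm), default `c(0.49, 0.49, 0.5)`.
#' @param margin_mm Background margin around the phantom (mm).
#' @param side Which condyle the emitted landmarks name (`"R"` or `"L"`).
#' @param seed RNG seed for the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(a = 7, b = 7, c = 9, center = c(0, 0, 0),
                         cut_height_mm = -c / 2, neck_radius = 4,
                         neck_length = 12, bone_hu = 1200,
                         background_hu = 0, noise_sd = 0,
                         spacing = c(0.49, 0.49, 0.5), margin_mm = 2,
                         side = "R", seed = NULL) {
  if (any(c(a, b, c) <= 0)) stop("semi-axes must be > 0", call. = FALSE)
  if (bone_hu < 226 || bone_hu > 3071) {
    stop("'bone_hu' must lie in the bone segmentation range [226, 3071]",
         call. = FALSE)
  }
  if (cut_height_mm < -c || cut_height_mm > c) {
    stop("'cut_height_mm' must lie in [-c, c]", call. = FALSE)
  }
  if (any(spacing <= 0)) stop("'spacing' must be positive", call. = FALSE)
  structure(
    list(a = a, b = b, c = c, center = as.numeric(center),
         cut_height_mm = cut_height_mm, neck_radius = neck_radius,
         neck_length = neck_length, bone_hu = bone_hu,
         background_hu = background_hu, noise_sd = noise_sd,
         spacing = as.numeric(spacing), margin_mm = margin_mm,
         side = match.arg(side, c("R", "L")), seed = seed),
    class = "phantom_spec"
  )
}

# rasterize one head+neck into an existing logical array
rasterize_condyle <- function(xs, ys, zs, a, b, c, center, z_cut,
                              neck_radius, neck_length, sz) {
  ex <- ((xs - center[1]) / a)^2
  ey <- ((ys - center[2]) / b)^2
  ez <- ((zs - center[3]) / c)^2
  head <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
  # neck strictly below the cut plane: top at z_cut - 0.6 voxel so no neck
  # voxel center can sit on the kept side of the plane
  neck_top <- z_cut - 0.6 * sz
  rx <- (xs - center[1])^2
  ry <- (ys - center[2])^2
  in_rad <- outer(rx, ry, `+`) <= neck_radius^2
  in_z <- zs >= (center[3] - c - neck_length) & zs <= neck_top
  neck <- outer(in_rad, in_z, `&`)
  head | neck
}

#' Build a single-condyle voxel phantom with analytic truth
#'
#' Voxelizes the [phantom_spec()] geometry and emits a co-registered
#' landmark set: Cd at the head apex, FP on the anterior neck surface at
#' the cut height, Po/Or forming an exactly horizontal Frankfurt quad above
#' the head, and Me far inferior (fixing the Frankfurt orientation). The
#' truth record carries the analytic head volume above the cut,
#' `ellipsoid_cap_volume(a, b, c, cut_height_mm)`.
#'
#' @param spec A `phantom_spec`.
#' @return List with elements `volume` (a `voxel_volume`), `landmarks`
#'   (a `landmark_set`) and `truth` (analytic record).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  ctr <- spec$center
  rmax <- max(spec$a, spec$neck_radius)
  lo <- ctr - c(rmax, max(spec$b, spec$neck_radius),
                spec$c + spec$neck_length) - spec$margin_mm
  hi <- ctr + c(rmax, max(spec$b, spec$neck_radius), spec$c) + spec$margin_mm
  d <- as.integer(ceiling((hi - lo) / sp)) + 2L
  if (any(d < 5L)) stop("phantom grid degenerate", call. = FALSE)
  # half-voxel z offset = midpoint (pixel-center) sampling convention:
  # voxel-center layers straddle the horizontal cut plane symmetrically
  # instead of coinciding with it, which would turn the kept boundary
  # layer into a half-voxel systematic bias
  origin <- lo - c(0, 0, 0.5) * sp
  xs <- origin[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(d[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(d[3]) - 1) * sp[3]
  z_cut <- ctr[3] + spec$cut_height_mm
  inside <- rasterize_condyle(xs, ys, zs, spec$a, spec$b, spec$c, ctr,
                              z_cut, spec$neck_radius, spec$neck_length,
                              sp[3])
  values <- array(spec$background_hu, dim = d)
  values[inside] <- spec$bone_hu
  if (spec$noise_sd > 0) {
    values <- values + with_seed(spec$seed,
                                 array(stats::rnorm(prod(d), 0, spec$noise_sd),
                                       dim = d))
  }
  vol <- voxel_volume(values, spacing = sp, origin = origin)
  s <- spec$side
  frankfurt_z <- ctr[3] + spec$c + 10
  lms <- list(
    c(ctr[1] + 55, ctr[2] - 25, frankfurt_z),  # Po_R
    c(ctr[1] - 55, ctr[2] - 25, frankfurt_z),  # Po_L
    c(ctr[1] + 32, ctr[2] + 55, frankfurt_z),  # Or_R
    c(ctr[1] - 32, ctr[2] + 55, frankfurt_z),  # Or_L
    c(ctr[1], ctr[2], ctr[3] + spec$c),        # Cd: head apex
    c(ctr[1], ctr[2] + spec$neck_radius, z_cut),  # FP: anterior neck @ cut
    c(ctr[1], ctr[2] - 10, ctr[3] - spec$c - 70)  # Me: far inferior
  )
  names(lms) <- c("Po_R", "Po_L", "Or_R", "Or_L",
                  paste0("Cd_", s), paste0("FP_", s), "Me")
  lm <- do.call(landmark_set, lms)
  list(
    volume = vol,
    landmarks = lm,
    truth = list(
      head_volume_mm3 = ellipsoid_cap_volume(spec$a, spec$b, spec$c,
                                             spec$cut_height_mm),
      full_ellipsoid_mm3 = 4 / 3 * pi * spec$a * spec$b * spec$c,
      cut_height_mm = spec$cut_height_mm,
      cut_z_world = z_cut,
      side = s
    )
  )
}

# direction at angle phi (deg) from straight-down (-z), tilted toward +y
ray_down <- function(phi_deg) {
  c(0, sin(deg2rad(phi_deg)), -cos(deg2rad(phi_deg)))
}

#' Full synthetic cephalometric landmark geometry
#'
#' Constructs a landmark set realizing prescribed ANB, divergence and total
#' gonial angles exactly (to floating point), with the Frankfurt quad
#' horizontal and all sign conventions satisfied. Bilateral condylion
#' positions are derived from gonion and the gonial angle, so phantom heads
#' can be centered below them. Geometry is synthetic: distances are
#' skull-like but only the angle contracts are exact.
#'
#' @param anb_deg Target signed ANB (degrees).
#' @param divergence_deg Target divergence (degrees, 0-90).
#' @param gonial_deg Target total gonial angle (degrees, 0-180).
#' @param go_halfwidth Half-distance between the gonions (mm).
#' @param ramus_mm,body_mm Ramus (Go-Cd) and body (mid-Go to Me) lengths (mm).
#' @return A `landmark_set` with Po, Or, A, B, N, Ans, Pns, Me, Go and Cd
#'   (both sides).
#' @export
make_cephalo_landmarks <- function(anb_deg = 2, divergence_deg = 41,
                                   gonial_deg = 120, go_halfwidth = 42,
                                   ramus_mm = 50, body_mm = 95) {
  d <- divergence_deg
  g <- gonial_deg
  go_r <- c(go_halfwidth, -12, -45)
  go_l <- c(-go_halfwidth, -12, -45)
  go_mid <- c(0, -12, -45)
  v <- c(0, cos(deg2rad(d)), -sin(deg2rad(d)))  # mid-Go -> Me direction
  me <- go_mid + body_mm * v
  # ramus direction: rotate unit(Go -> Me) by the gonial angle toward
  # superior, in the plane spanned with +z
  cd_from <- function(go) {
    u <- unit(me - go)
    mref <- c(0, 0, 1) - sum(c(0, 0, 1) * u) * u
    m <- unit(mref)
    w <- cos(deg2rad(g)) * u + sin(deg2rad(g)) * m
    go + ramus_mm * w
  }
  cd_r <- cd_from(go_r)
  cd_l <- cd_from(go_l)
  z_mx <- me[3] + 50
  ans <- c(0, 62, z_mx)
  pns <- c(0, 12, z_mx)
  n <- c(0, 34, z_mx + 35)  # posterior to mid(Ans, Pns): anterior axis = +y
  a_pt <- n + 60 * ray_down(5 + anb_deg)
  b_pt <- n + 60 * ray_down(5)
  landmark_set(
    Po_R = c(55, -25, 15), Po_L = c(-55, -25, 15),
    Or_R = c(32, 55, 15), Or_L = c(-32, 55, 15),
    A = a_pt, B = b_pt, N = n, Ans = ans, Pns = pns, Me = me,
    Go_R = go_r, Go_L = go_l, Cd_R = cd_r, Cd_L = cd_l
  )
}

#' Bilateral condyle phantom with full cephalometric landmarks
#'
#' Renders two mirrored condyle phantoms in one grid, centered under the
#' condylion positions of [make_cephalo_landmarks()], and returns analytic
#' truths per side. The voxel grid is constructed symmetric about the
#' midsagittal plane, so a perfectly mirrored pair voxelizes to exactly
#' equal volumes. FP landmarks are placed at the cut height of each side.
#'
#' @param spec A `phantom_spec` (its `center` and `side` are ignored; head
#'   geometry, HU, noise and spacing are used).
#' @param anb_deg,divergence_deg,gonial_deg Angles passed to
#'   [make_cephalo_landmarks()].
#' @param scale_left Per-axis scale factor of the left head (1 = exact
#'   mirror).
#' @param go_halfwidth Half-distance between the gonions (mm); controls
#'   the lateral separation of the two condyles.
#' @return List with `volume`, `landmarks` and `truth` (a list with `R`
#'   and `L` analytic records).
#' @export
make_bilateral_phantom <- function(spec, anb_deg = 2, divergence_deg = 41,
                                   gonial_deg = 120, scale_left = 1,
                                   go_halfwidth = 42) {
  stopifnot(inherits(spec, "phantom_spec"))
  lm0 <- make_cephalo_landmarks(anb_deg = anb_deg,
                                divergence_deg = divergence_deg,
                                gonial_deg = gonial_deg,
                                go_halfwidth = go_halfwidth)
  cd_r <- lm_point(lm0, "Cd_R")
  cd_l <- lm_point(lm0, "Cd_L")
  sL <- scale_left
  ctr_r <- cd_r - c(0, 0, spec$c)
  ctr_l <- cd_l - c(0, 0, spec$c * sL)
  reach_x_r <- max(spec$a, spec$neck_radius)
  reach_x_l <- max(spec$a * sL, spec$neck_radius)
  if (ctr_r[1] - reach_x_r < 0 || ctr_l[1] + reach_x_l > 0) {
    stop("bilateral phantoms overlap the midline", call. = FALSE)
  }
  sp <- spec$spacing
  # grid symmetric about x = 0: voxel centers mirror onto voxel centers
  half_w <- max(ctr_r[1] + reach_x_r, -(ctr_l[1] - reach_x_l)) +
    spec$margin_mm
  nx_half <- ceiling(half_w / sp[1] + 0.5)
  nx <- as.integer(2 * nx_half)
  # (i - 1) - (nx - 1)/2 is exact in floating point, so the x centers are
  # an exactly sign-symmetric set and mirrored masks voxelize identically
  xs <- ((seq_len(nx) - 1) - (nx - 1) / 2) * sp[1]
  origin_x <- xs[1]
  ylo <- min(ctr_r[2], ctr_l[2]) - max(spec$b * max(1, sL), spec$neck_radius) -
    spec$margin_mm
  yhi <- max(ctr_r[2], ctr_l[2]) + max(spec$b * max(1, sL), spec$neck_radius) +
    spec$margin_mm
  zlo <- min(ctr_r[3] - spec$c, ctr_l[3] - spec$c * sL) - spec$neck_length -
    spec$margin_mm
  zhi <- max(ctr_r[3] + spec$c, ctr_l[3] + spec$c * sL) + spec$margin_mm
  ny <- as.integer(ceiling((yhi - ylo) / sp[2])) + 1L
  nz <- as.integer(ceiling((zhi - zlo) / sp[3])) + 2L
  # same midpoint z convention as make_phantom: cut planes sit between
  # voxel-center layers, not on them
  origin <- c(origin_x, ylo, zlo - 0.5 * sp[3])
  ys <- origin[2] + (seq_len(ny) - 1) * sp[2]
  zs <- origin[3] + (seq_len(nz) - 1) * sp[3]
  z_cut_r <- ctr_r[3] + spec$cut_height_mm
  z_cut_l <- ctr_l[3] + spec$cut_height_mm * sL
  inside_r <- rasterize_condyle(xs, ys, zs, spec$a, spec$b, spec$c, ctr_r,
                                z_cut_r, spec$neck_radius, spec$neck_length,
                                sp[3])
  inside_l <- rasterize_condyle(xs, ys, zs, spec$a * sL, spec$b * sL,
                                spec$c * sL, ctr_l, z_cut_l,
                                spec$neck_radius, spec$neck_length, sp[3])
  if (any(inside_r & inside_l)) {
    stop("bilateral phantoms overlap", call. = FALSE)
  }
  values <- array(spec$background_hu, dim = c(nx, ny, nz))
  values[inside_r | inside_l] <- spec$bone_hu
  if (spec$noise_sd > 0) {
    values <- values +
      with_seed(spec$seed,
                array(stats::rnorm(length(values), 0, spec$noise_sd),
                      dim = dim(values)))
  }
  vol <- voxel_volume(values, spacing = sp, origin = origin)
  m <- unclass(lm0)
  extra <- rbind(
    FP_R = c(ctr_r[1], ctr_r[2] + spec$neck_radius, z_cut_r),
    FP_L = c(ctr_l[1], ctr_l[2] + spec$neck_radius, z_cut_l),
    Cd_R = ctr_r + c(0, 0, spec$c),
    Cd_L = ctr_l + c(0, 0, spec$c * sL)
  )
  m <- rbind(m[setdiff(rownames(m), rownames(extra)), , drop = FALSE], extra)
  lm <- landmark_set(m)
  truth_side <- function(scale, h) {
    list(head_volume_mm3 = ellipsoid_cap_volume(spec$a * scale,
                                                spec$b * scale,
                                                spec$c * scale, h),
         cut_height_mm = h)
  }
  list(
    volume = vol,
    landmarks = lm,
    truth = list(R = truth_side(1, spec$cut_height_mm),
                 L = truth_side(sL, spec$cut_height_mm * sL))
  )
}
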