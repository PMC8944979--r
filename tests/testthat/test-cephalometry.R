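test_that("fit_plane interpolates coplanar points and rejects degenerate input", {
  pl <- fit_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  pl2 <- fit_plane(rbind(c(0, 0, 2), c(3, 0, 2), c(0, 5, 2), c(4, 4, 2)))
  expect_equal(pl2$max_residual, 0, tolerance = 1e-12)
  pts <- rbind(A = c(0, 0, 0), B = c(1, 1, 1), C = c(2, 2, 2))
  expect_error(fit_plane(pts), "collinear.*A, B, C")
})

test_that("fit_plane equals the total-least-squares solution on noisy points", {
  # four points with +/- 0.1 mm out-of-plane perturbation
  pts <- rbind(c(10, 0, 0.1), c(-10, 0, -0.1), c(0, 10, -0.1), c(0, -10, 0.1))
  pl <- fit_plane(pts)
  # oracle 1: smallest eigenvector of the scatter matrix
  ctr <- colMeans(pts)
  S <- crossprod(sweep(pts, 2, ctr))
  ev <- eigen(S, symmetric = TRUE)
  n_oracle <- ev$vectors[, 3]
  expect_equal(abs(sum(pl$normal * n_oracle)), 1, tolerance = 1e-9)
  expect_equal(sum(pl$normal * (pl$p0 - ctr)), 0, tolerance = 1e-9)
  # oracle 2: direct numeric minimization of sum of squared distances
  ssd <- function(par) {
    n <- c(cos(par[1]) * sin(par[2]), sin(par[1]) * sin(par[2]), cos(par[2]))
    sum((pts %*% n - par[3])^2)
  }
  opt <- optim(c(0, 0.1, 0), ssd, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(sum(signed_distance(pl, pts)^2), opt$value, tolerance = 1e-9)
})

test_that("frankfurt plane honors the Me-below orientation contract", {
  lm <- landmark_set(Po_R = c(55, -25, 0), Po_L = c(-55, -25, 0),
                     Or_R = c(32, 55, 0), Or_L = c(-32, 55, 0),
                     Me = c(0, -20, -80))
  fp <- frankfurt_plane(lm)
  expect_equal(fp$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(signed_distance(fp, c(0, -20, -80)), -80, tolerance = 1e-9)
  expect_error(frankfurt_plane(landmark_set(Po_L = c(-55, -25, 0),
                                            Or_R = c(32, 55, 0),
                                            Or_L = c(-32, 55, 0))),
               "missing landmark Po_R")
})

test_that("frankfurt plane is equivariant under rigid motion", {
  lm <- full_landmarks()
  R <- rot3(c(1, 0, 0), 30)
  fp0 <- frankfurt_plane(lm)
  fp1 <- frankfurt_plane(transform_landmarks(lm, R, center = c(0, 10, -5),
                                             translation = c(3, -2, 7)))
  expect_equal(as.vector(R %*% fp0$normal), fp1$normal, tolerance = 1e-9)
  expect_equal(fp1$rmse, fp0$rmse, tolerance = 1e-9)
})

test_that("condylar cut plane passes through FP, parallel, head-side positive", {
  lm <- landmark_set(FP_R = c(50, 30, -5), Cd_R = c(50, 28, 3))
  fr <- plane(c(0, 0, 0), c(0, 0, 1))
  cut <- condylar_cut_plane(lm, "R", fr)
  expect_equal(cut$p0, c(50, 30, -5))
  expect_equal(cut$normal, c(0, 0, 1))
  # condylion below FP: normal flips so the head side stays positive
  lm2 <- landmark_set(FP_R = c(50, 30, -5), Cd_R = c(50, 28, -12))
  cut2 <- condylar_cut_plane(lm2, "R", fr)
  expect_equal(cut2$normal, c(0, 0, -1))
  expect_gte(signed_distance(cut2, c(50, 28, -12)), 0)
  expect_error(condylar_cut_plane(landmark_set(FP_L = c(0, 0, 0)), "R", fr),
               "missing landmark FP_R")
})

test_that("ANB angle magnitude and sign follow the anterior-axis convention", {
  # +x fallback axis: A anterior to B by projection -> +45 degrees
  lm <- landmark_set(N = c(0, 0, 0), A = c(1, 0, -1), B = c(0, 0, -1))
  expect_equal(anb_angle(lm), 45, tolerance = 1e-9)
  lm_neg <- landmark_set(N = c(0, 0, 0), A = c(-1, 0, -1), B = c(0, 0, -1))
  expect_equal(anb_angle(lm_neg), -45, tolerance = 1e-9)
  # collinear on the same ray -> 0
  lm0 <- landmark_set(N = c(0, 0, 0), A = c(0, 0, -1), B = c(0, 0, -2))
  expect_equal(anb_angle(lm0), 0, tolerance = 1e-9)
  expect_error(anb_angle(landmark_set(N = c(0, 0, 0), A = c(0, 0, 0),
                                      B = c(1, 1, 1))), "coincides")
})

test_that("divergence angle folds to [0, 90] and hits constructed values", {
  base <- list(Ans = c(0, 10, 0), Pns = c(0, 0, 0),
               Go_R = c(5, 0, 0), Go_L = c(-5, 0, 0))
  lm_par <- do.call(landmark_set, c(base, list(Me = c(0, 40, 0))))
  expect_equal(divergence_angle(lm_par), 0, tolerance = 1e-9)
  lm_perp <- do.call(landmark_set, c(base, list(Me = c(0, 0, -40))))
  expect_equal(divergence_angle(lm_perp), 90, tolerance = 1e-9)
  me41 <- 50 * c(0, cos(41 * pi / 180), -sin(41 * pi / 180))
  lm41 <- do.call(landmark_set, c(base, list(Me = me41)))
  expect_equal(divergence_angle(lm41), 41, tolerance = 1e-9)
  # reversing the maxillary line direction must not push it past 90
  lm_rev <- do.call(landmark_set, c(
    list(Ans = c(0, 0, 0), Pns = c(0, 10, 0), Me = me41),
    base[c("Go_R", "Go_L")]))
  expect_equal(divergence_angle(lm_rev), 41, tolerance = 1e-9)
})

test_that("gonial angle preserves obtuse values and detects degenerate input", {
  lm90 <- landmark_set(Cd_R = c(0, 0, 10), Go_R = c(0, 0, 0),
                       Me = c(0, 10, 0))
  expect_equal(gonial_angle(lm90, "R"), 90, tolerance = 1e-9)
  # constructed 120 stays 120, not 60
  lm <- full_landmarks(gon = 120)
  expect_equal(gonial_angle(lm, "R"), 120, tolerance = 1e-9)
  expect_equal(gonial_angle(lm, "L"), 120, tolerance = 1e-9)
  expect_error(gonial_angle(landmark_set(Cd_R = c(0, 0, 10),
                                         Go_R = c(0, 1, 0), Me = c(0, 1, 0)),
                            "R"), "coincident")
})

test_that("constructed landmark geometry realizes requested angles exactly", {
  for (ang in list(c(-3, 38, 112), c(1.5, 41, 120), c(6.5, 47.5, 131))) {
    lm <- make_cephalo_landmarks(anb_deg = ang[1], divergence_deg = ang[2],
                                 gonial_deg = ang[3])
    m <- measure_cephalometrics(lm)
    expect_equal(m$anb_deg, ang[1], tolerance = 1e-9)
    expect_equal(m$divergence_deg, ang[2], tolerance = 1e-9)
    expect_equal(m$gonial_deg_mean, ang[3], tolerance = 1e-9)
  }
  # at ANB = 0 the angle sits where acos loses precision; still tiny
  m0 <- measure_cephalometrics(make_cephalo_landmarks(anb_deg = 0))
  expect_lt(abs(m0$anb_deg), 1e-5)
})

test_that("all angles are invariant under rigid motion and uniform scaling", {
  lm <- full_landmarks()
  m0 <- unlist(measure_cephalometrics(lm))
  set.seed(41)
  for (i in 1:5) {
    R <- rot3(rnorm(3), runif(1, 5, 170))
    moved <- transform_landmarks(lm, R, center = rnorm(3, 0, 20),
                                 translation = rnorm(3, 0, 50))
    expect_lt(max(abs(unlist(measure_cephalometrics(moved)) - m0)), 1e-7)
  }
  scaled <- landmark_set(unclass(lm) * 2.7)
  expect_equal(unlist(measure_cephalometrics(scaled)), m0, tolerance = 1e-9)
})

test_that("mirror-symmetric landmarks give equal left and right gonial angles", {
  lm <- full_landmarks()
  expect_equal(gonial_angle(lm, "R"), gonial_angle(lm, "L"),
               tolerance = 1e-12)
})
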