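# rotation matrix about a (not necessarily unit) axis, Rodrigues form
rot3 <- function(axis, angle_deg) {
  k <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# a small complete landmark set with known, irregular angles
full_landmarks <- function(anb = 3.2, div = 44, gon = 118) {
  make_cephalo_landmarks(anb_deg = anb, divergence_deg = div,
                         gonial_deg = gon)
}

# minimal valid cohort table built by hand
tiny_cohort <- function(volumes = c(600, 800, 700, 900, 500, 750)) {
  n <- length(volumes)
  stopifnot(n %% 2 == 0)
  data.frame(
    subject_id = rep(sprintf("P%02d", seq_len(n / 2)), each = 2),
    side = rep(c("R", "L"), n / 2),
    volume_mm3 = volumes,
    sex = rep(rep(c("F", "M"), length.out = n / 2), each = 2),
    age_years = rep(30, n),
    anb_deg = rep(2, n),
    divergence_deg = rep(41, n),
    gonial_deg = rep(120, n)
  )
}
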