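test_that("cylinder quadrature lattice is normalized, centered and symmetric", {
  t <- trajectory(c(1, 2, 3), c(0.2, 0.9, -0.1), 30, 6)
  cs <- cylinder_samples(t, 0.5, 3L)
  expect_equal(sum(cs$weights), 1, tolerance = 1e-12)
  # rings = 1: all points on the centerline
  cs1 <- cylinder_samples(t, 1, 1L)
  rel <- cs1$points - matrix(t$entry, nrow(cs1$points), 3, byrow = TRUE)
  s <- rel %*% t$direction
  perp <- sqrt(rowSums((rel - s %*% t(t$direction))^2))
  expect_lt(max(perp), 1e-9)
  # linear field: weighted mean equals the field at the cylinder centroid
  g <- function(p) 2 * p[, 1] + 3 * p[, 2] - p[, 3] + 5
  centroid <- t$entry + t$length / 2 * t$direction
  expect_equal(sum(cs$weights * g(cs$points)),
               g(matrix(centroid, 1)), tolerance = 1e-6)
})

test_that("mean corridor CT value is exact on constant and symmetric split fields", {
  sp <- 1
  n <- 41L
  xs <- (seq_len(n) - (n + 1) / 2) * sp
  a <- diag(c(sp, sp, sp, 1)); a[1:3, 4] <- xs[1]
  vu <- ct_volume(array(1000, c(n, n, n)), a)
  t <- trajectory(c(0, -10, 0), c(0, 1, 0), 20, 6)
  expect_equal(mean_ct_value(t, vu), 1000, tolerance = 1e-9)
  # 1000/2000 half-spaces meeting at the corridor's axial midpoint
  # (split plane perpendicular to the axis, 1500 on the boundary row)
  hu <- array(rep(ifelse(xs < 0, 1000, ifelse(xs > 0, 2000, 1500)),
                  each = n), c(n, n, n))
  vs <- ct_volume(hu, a)
  expect_equal(mean_ct_value(t, vs), 1500, tolerance = 15)
  expect_error(mean_ct_value(trajectory(c(0, 0, 0), c(0, 1, 0), 100, 6),
                             vu), "exits the scanned grid")
})

test_that("default corridor sampling agrees with a much denser quadrature", {
  ph <- default_phantom()
  f <- frame_from_truth(ph$truth, "left")
  mp <- plan_manual(ph$ct, ph$labels, f, "left", dmap = default_dmap())
  coarse <- mean_ct_value(mp$trajectory, ph$ct)
  dense <- mean_ct_value(mp$trajectory, ph$ct,
                         step_axial = min(ph$ct$spacing) / 8, rings = 6L)
  expect_lt(abs(coarse - dense) / dense, 0.005)
})

test_that("measurements match an independent vector-algebra oracle", {
  set.seed(21)
  f <- standard_frame()
  for (i in 1:50) {
    t <- random_trajectory()
    m <- measure_trajectory(t, f)
    o <- oracle_measure(t, f)
    expect_equal(m$d, o$d, tolerance = 1e-9)
    expect_equal(m$theta, o$theta, tolerance = 1e-9)
    expect_equal(m$d_prime, o$d_prime, tolerance = 1e-9)
    expect_equal(m$theta_prime, o$theta_prime, tolerance = 1e-9)
    # derived angles are exact identities
    expect_identical(m$abduction, 90 - m$theta)
    expect_identical(m$craniocaudal, m$theta_prime - 90)
  }
})

test_that("measure -> reconstruct -> measure is a fixed point", {
  set.seed(31)
  f <- standard_frame()
  for (i in 1:100) {
    t <- random_trajectory()
    m <- measure_trajectory(t, f)
    t2 <- reconstruct_trajectory(m, t$entry, f, t$length, t$diameter)
    m2 <- measure_trajectory(t2, f)
    expect_equal(m2$d, m$d, tolerance = 1e-6)
    expect_equal(m2$theta, m$theta, tolerance = 1e-6)
    expect_equal(m2$d_prime, m$d_prime, tolerance = 1e-6)
    expect_equal(m2$theta_prime, m$theta_prime, tolerance = 1e-6)
  }
})

test_that("axis-aligned and degenerate cases behave as documented", {
  f <- standard_frame()
  # straight anterior, parallel to the endplate: no abduction, no tilt
  t <- trajectory(c(-15, -30, 0), c(0, 1, 0), 30, 6)
  m <- measure_trajectory(t, f)
  expect_equal(m$theta, 90)
  expect_equal(m$theta_prime, 90)
  expect_equal(m$abduction, 0)
  expect_equal(m$craniocaudal, 0)
  # reconstruction at 90/90 returns the pure anterior axis
  t0 <- reconstruct_trajectory(list(theta = 90, theta_prime = 90),
                               c(-15, -30, 0), f)
  expect_equal(t0$direction, c(0, 1, 0), tolerance = 1e-12)
  expect_lt(abs(sum(t0$direction * f$midline_normal)), 1e-12)
  expect_lt(abs(sum(t0$direction * f$endplate_normal)), 1e-12)
  # screw along the craniocaudal axis has no axial projection
  tz <- trajectory(c(-15, -30, 0), c(0, 0, 1), 30, 6)
  expect_error(measure_trajectory(tz, f), "degenerate axial")
  expect_error(reconstruct_trajectory(list(theta = 200, theta_prime = 90),
                                      c(-15, -30, 0), f),
               "inconsistent angles")
})

test_that("measurements are invariant under joint rigid motions", {
  set.seed(41)
  f <- standard_frame()
  for (i in 1:10) {
    t <- random_trajectory()
    m <- measure_trajectory(t, f)
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    sft <- runif(3, -20, 20)
    t2 <- trajectory(drop(R %*% t$entry) + sft, drop(R %*% t$direction),
                     t$length, t$diameter)
    f2 <- vertebral_frame(drop(R %*% f$midline_point) + sft,
                          drop(R %*% f$midline_normal),
                          drop(R %*% f$endplate_point) + sft,
                          drop(R %*% f$endplate_normal),
                          drop(R %*% f$axial_normal), f$side)
    m2 <- measure_trajectory(t2, f2)
    expect_equal(m2$d, m$d, tolerance = 1e-9)
    expect_equal(m2$theta, m$theta, tolerance = 1e-9)
    expect_equal(m2$d_prime, m$d_prime, tolerance = 1e-9)
    expect_equal(m2$theta_prime, m$theta_prime, tolerance = 1e-9)
  }
})

test_that("placement error is the signed difference of measurements", {
  f <- standard_frame()
  t <- trajectory(c(-15, -30, 2), c(0.2, 1, -0.1) / sqrt(1.05), 30, 6)
  m <- measure_trajectory(t, f)
  pe <- placement_error(m, m)
  expect_equal(pe$displacement_error, 0)
  expect_equal(pe$angle_error, 0)
  # group means of planned vs actual axial distance: 20.54 - 20.44
  planned <- list(d = 20.44, theta = 58.11)
  actual <- list(d = 20.54, theta = 57.85)
  pe2 <- placement_error(planned, actual)
  expect_equal(pe2$displacement_error, 0.10, tolerance = 1e-9)
  expect_equal(pe2$angle_error, -0.26, tolerance = 1e-9)
  # antisymmetry
  pe3 <- placement_error(actual, planned)
  expect_equal(pe3$displacement_error, -pe2$displacement_error)
  expect_equal(pe3$angle_error, -pe2$angle_error)
})

test_that("trajectory JSON and guide export round trip", {
  t <- trajectory(c(-15, -30, 2), c(0.2, 1, -0.1), 30, 6)
  fj <- tempfile(fileext = ".json")
  write_trajectory(t, fj, side = "left")
  t2 <- read_trajectory(fj)
  expect_equal(t2$entry, t$entry)
  expect_equal(t2$direction, t$direction, tolerance = 1e-12)
  fg <- tempfile(fileext = ".csv")
  export_guide(t, fg)
  df <- read.csv(fg)
  expect_equal(df$point, c("entry", "tip"))
  expect_equal(unlist(df[2, 2:4], use.names = FALSE), trajectory_tip(t),
               tolerance = 1e-9)
  unlink(c(fj, fg))
})
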