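coarse_settings <- function(refine = FALSE)
  search_settings(entry_grid_step = 1.5, cone_half_angle = 10,
                  angular_step = 2.5, refine = refine,
                  refine_min_step = 0.25)

test_that("the narrowest pedicle section is found at the waist", {
  ph <- default_phantom()
  for (side in c("left", "right")) {
    ms <- find_min_pedicle_section(ph$labels, side)
    truth <- ph$truth$min_section_centroids[[side]]
    # hourglass waist radius 4.5 mm: area ~ pi r^2
    expect_lt(abs(ms$area - pi * 4.5^2) / (pi * 4.5^2), 0.05)
    expect_lt(sqrt(sum((ms$centroid - truth)^2)),
              sqrt(3) * max(ph$labels$spacing))
    # centroid lies inside the pedicle (waist voxels carry the ROI label)
    lab <- sample_label(ph$labels, ms$centroid)
    expect_true(lab %in% pediplan:::.side_labels(side))
    # axis aligns with the ground-truth pedicle axis
    tru_u <- ph$truth$pedicle_axes[[side]]$direction
    ang <- acos(min(1, abs(sum(ms$axis * tru_u)))) * 180 / pi
    expect_lt(ang, 3)
  }
})

test_that("area ties on a constant-radius pedicle resolve to mid-length", {
  # synthetic straight pedicle: constant-radius cylinder along y
  sp <- 1
  nx <- 21L; ny <- 41L; nz <- 21L
  xs <- (seq_len(nx) - 11) * sp
  ys <- (seq_len(ny) - 21) * sp
  zs <- (seq_len(nz) - 11) * sp
  lab <- array(0L, c(nx, ny, nz))
  disk <- outer(xs^2, zs^2, "+") <= 5^2
  for (j in seq_len(ny)) if (abs(ys[j]) <= 15) lab[, j, ][disk] <- 3L
  affine <- diag(c(sp, sp, sp, 1)); affine[1:3, 4] <- c(xs[1], ys[1], zs[1])
  l <- label_volume(lab, affine)
  ms <- find_min_pedicle_section(l, "left")
  # every interior station ties; the tie rule picks the mid-length slab
  expect_lt(abs(ms$centroid[2]), 1)
  expect_lt(abs(abs(ms$axis[2]) - 1), 1e-6)
})

test_that("disconnected pedicle labels are rejected", {
  lab <- array(0L, c(10, 10, 10))
  lab[2:3, 2:3, 2:3] <- 3L
  lab[8:9, 8:9, 8:9] <- 3L
  l <- label_volume(lab, diag(4))
  expect_error(find_min_pedicle_section(l, "left"), "disconnected")
})

test_that("the manual plan runs parallel to the endplate through the waist midpoint", {
  ph <- default_phantom()
  dm <- default_dmap()
  for (side in c("left", "right")) {
    f <- frame_from_truth(ph$truth, side)
    mp <- plan_manual(ph$ct, ph$labels, f, side, dmap = dm)
    expect_true(mp$feasibility$feasible)
    m <- measure_trajectory(mp$trajectory, f)
    expect_lt(abs(m$craniocaudal), 0.5)
    # centerline passes within a voxel of the min-section centroid
    ms <- find_min_pedicle_section(ph$labels, side)
    rel <- ms$centroid - mp$trajectory$entry
    s <- sum(rel * mp$trajectory$direction)
    miss <- sqrt(sum((rel - s * mp$trajectory$direction)^2))
    expect_lt(miss, sqrt(3) * max(ph$labels$spacing))
    # recomputing the corridor mean reproduces the stored score
    expect_equal(mp$mean_hu, mean_ct_value(mp$trajectory, ph$ct),
                 tolerance = 1e-9)
  }
})

test_that("left and right manual plans mirror across the midline", {
  ph <- default_phantom()
  dm <- default_dmap()
  fl <- frame_from_truth(ph$truth, "left")
  fr <- frame_from_truth(ph$truth, "right")
  mpl <- plan_manual(ph$ct, ph$labels, fl, "left", dmap = dm)
  mpr <- plan_manual(ph$ct, ph$labels, fr, "right", dmap = dm)
  el <- mpl$trajectory$entry; er <- mpr$trajectory$entry
  vox <- sqrt(3) * max(ph$labels$spacing)
  expect_lt(abs(el[1] + er[1]), vox)
  expect_lt(abs(el[2] - er[2]), vox)
  expect_lt(abs(el[3] - er[3]), vox)
  ml <- measure_trajectory(mpl$trajectory, fl)
  mr <- measure_trajectory(mpr$trajectory, fr)
  expect_lt(abs(ml$d - mr$d), vox)
  expect_lt(abs(abs(ml$abduction) - abs(mr$abduction)), 0.5)
})

test_that("the automatic planner is deterministic and matches the enumeration oracle", {
  ph <- default_phantom()
  dm <- default_dmap()
  f <- frame_from_truth(ph$truth, "left")
  st <- coarse_settings(refine = FALSE)
  a1 <- plan_auto(ph$ct, ph$labels, f, "left", settings = st, dmap = dm)
  a2 <- plan_auto(ph$ct, ph$labels, f, "left", settings = st, dmap = dm)
  expect_identical(a1$trajectory, a2$trajectory)
  expect_identical(a1$mean_hu, a2$mean_hu)
  bf <- brute_force_plan(ph$ct, ph$labels, f, "left", settings = st,
                         dmap = dm)
  expect_identical(a1$trajectory, bf$trajectory)
  expect_identical(a1$mean_hu, bf$mean_hu)
  expect_true(a1$feasibility$feasible)
  # the exhaustive maximum dominates the manual member of the cone
  mp <- plan_manual(ph$ct, ph$labels, f, "left", dmap = dm)
  expect_gte(bf$mean_hu, mp$mean_hu)
  expect_equal(a1$mean_hu, mean_ct_value(a1$trajectory, ph$ct),
               tolerance = 1e-9)
})

test_that("a constant objective still yields a deterministic feasible plan", {
  ph <- default_phantom()
  dm <- default_dmap()
  f <- frame_from_truth(ph$truth, "left")
  vu <- uniform_ct(ph$labels, 1500)
  st <- coarse_settings(refine = FALSE)
  a1 <- plan_auto(vu, ph$labels, f, "left", settings = st, dmap = dm)
  bf <- brute_force_plan(vu, ph$labels, f, "left", settings = st,
                         dmap = dm)
  expect_identical(a1$trajectory, bf$trajectory)  # shared tie rule
  expect_equal(a1$mean_hu, 1500, tolerance = 1e-9)
  expect_true(a1$feasibility$feasible)
})

test_that("a planted dense corridor is recovered by the refined search", {
  base <- phantom_spec(seed = 7)
  ax <- generate_phantom(base)$truth$pedicle_axes$left
  corr <- list(point = ax$point + c(0, 0, 2), direction = ax$direction,
               radius = 2.5, hu_boost = 500)
  ph <- generate_phantom(phantom_spec(seed = 7, corridor = corr))
  dm <- distance_map(ph$labels, bone_labels())
  f <- frame_from_truth(ph$truth, "left")
  ap <- plan_auto(ph$ct, ph$labels, f, "left",
                  settings = coarse_settings(refine = TRUE), dmap = dm)
  w <- corr$direction
  mid <- ap$trajectory$entry + ap$trajectory$length / 2 *
    ap$trajectory$direction
  rel <- mid - corr$point
  offset <- sqrt(sum((rel - sum(rel * w) * w)^2))
  ang <- acos(min(1, sum(ap$trajectory$direction * w))) * 180 / pi
  expect_lt(offset, 2)
  expect_lt(ang, 5)
  # boosting a feasible corridor never lowers the attained objective
  ph0 <- generate_phantom(phantom_spec(seed = 7))
  a0 <- plan_auto(ph0$ct, ph0$labels, f, "left",
                  settings = coarse_settings(refine = FALSE),
                  dmap = distance_map(ph0$labels, bone_labels()))
  a5 <- plan_auto(ph$ct, ph$labels, f, "left",
                  settings = coarse_settings(refine = FALSE), dmap = dm)
  expect_gte(a5$mean_hu, a0$mean_hu)
})

test_that("an oversized screw is reported as having no feasible trajectory", {
  ph <- coarse_phantom()
  dm <- coarse_dmap()
  f <- frame_from_truth(ph$truth, "left")
  expect_error(plan_auto(ph$ct, ph$labels, f, "left", length = 80,
                         settings = coarse_settings(), dmap = dm),
               "no feasible candidate")
})

test_that("screw sizing follows the 80% fill rule over standard sizes", {
  expect_equal(screw_size(8, 40), list(diameter = 6, length = 30))
  expect_equal(screw_size(9.5, 55)$diameter, 7)
  expect_equal(screw_size(8, 55)$length, 40)
  expect_error(screw_size(5, 40), "no admissible diameter")
  expect_error(screw_size(8, 20), "no admissible length")
  rec <- recommend_screw(default_phantom()$labels, "left")
  expect_true(rec$diameter %in% c(4.5, 5, 5.5, 6, 6.5, 7))
  expect_true(rec$length %in% c(25, 30, 35, 40, 45))
  expect_gte(rec$diameter, 6)   # 9 mm waist accommodates the 6 mm screw
  expect_gte(rec$length, 30)
})
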