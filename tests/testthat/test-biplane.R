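test_that("DLT calibration is exact on noise-free correspondences", {
  g0 <- make_projection_geometry(c(1, 0.2, 0.1), target = c(0, 0, 25))
  F8 <- default_fiducials(50)[seq(1, 16, by = 2), ]
  g <- calibrate_view(F8, project_points(g0, F8))
  expect_lte(g$reprojection_rms, 1e-6)
  # the calibrated matrix reprojects arbitrary points like the truth
  P <- cbind(runif(50, -20, 20), runif(50, -20, 20), runif(50, 0, 50))
  expect_equal(project_points(g, P), project_points(g0, P), tolerance = 1e-6)
})

test_that("DLT reprojection RMS tracks the detection noise level", {
  g0 <- make_projection_geometry(c(0, 1, 0), target = c(0, 0, 25))
  F16 <- default_fiducials(50)
  det <- project_points(g0, F16)
  set.seed(42)
  rms <- replicate(100, {
    calibrate_view(F16, det + matrix(rnorm(length(det), 0, 0.5), ncol = 2))$reprojection_rms
  })
  expect_true(all(rms >= 0.2 & rms <= 1.0))
})

test_that("degenerate calibration inputs are rejected", {
  g0 <- make_projection_geometry(c(1, 0, 0), target = c(0, 0, 25))
  F16 <- default_fiducials(50)
  expect_error(calibrate_view(F16[1:5, ], project_points(g0, F16[1:5, ])),
               "underdetermined")
  flat <- cbind(F16[, 1:2], 0)
  expect_error(calibrate_view(flat, project_points(g0, flat)), "coplanar")
})

test_that("calibration is equivariant under a rigid world transform", {
  g0 <- make_projection_geometry(c(1, 0.1, 0), target = c(0, 0, 25))
  F16 <- default_fiducials(50)
  det <- project_points(g0, F16) + matrix(rnorm(32, 0, 0.3), ncol = 2)
  rms0 <- calibrate_view(F16, det)$reprojection_rms
  R <- rotation_about_axis(c(1, 2, 3), 0.7)
  F_rot <- sweep(F16 %*% t(R), 2, c(5, -3, 10), "+")
  rms1 <- calibrate_view(F_rot, det)$reprojection_rms
  expect_equal(rms0, rms1, tolerance = 1e-9)
})

test_that("triangulation inverts exact projections to machine precision", {
  g1 <- make_projection_geometry(c(1, 0, 0), target = c(0, 0, 25))
  g2 <- make_projection_geometry(c(0, 1, 0), target = c(0, 0, 25))
  set.seed(3)
  P <- cbind(runif(1000, -20, 20), runif(1000, -20, 20), runif(1000, 0, 50))
  pa <- project_points(g1, P); pb <- project_points(g2, P)
  err <- vapply(seq_len(1000), function(i)
    sqrt(sum((triangulate_point(g1, g2, pa[i, ], pb[i, ])$point - P[i, ])^2)),
    numeric(1))
  expect_lt(max(err), 1e-6)
  # perturbing one detection yields a strictly positive reported residual
  tr <- triangulate_point(g1, g2, pa[1, ], pb[1, ] + c(1, 0))
  expect_gt(tr$residual, 0)
})

test_that("triangulation is the reprojection-error minimizer", {
  g1 <- make_projection_geometry(c(1, 0, 0), target = c(0, 0, 25))
  g2 <- make_projection_geometry(c(0.2, 1, 0.1), target = c(0, 0, 25))
  pt_a <- c(530, 480); pt_b <- c(500, 520)
  X <- triangulate_point(g1, g2, pt_a, pt_b)$point
  cost <- function(p) {
    sum((project_points(g1, rbind(p)) - pt_a)^2) +
      sum((project_points(g2, rbind(p)) - pt_b)^2)
  }
  c0 <- cost(X)
  for (d in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    for (h in c(-0.05, 0.05)) expect_gte(cost(X + h * d), c0 - 1e-9)
  }
})

test_that("near-parallel rays are rejected as ill-conditioned", {
  g1 <- make_projection_geometry(c(1, 0, 0), target = c(0, 0, 25))
  g2 <- make_projection_geometry(c(1, 0.001, 0), target = c(0, 0, 25))
  expect_error(triangulate_point(g1, g2, c(512, 512), c(512, 512)),
               "ill-conditioned")
})

test_that("boundary triangulation recovers cylinder geometry", {
  tr <- cyl_truth()
  g1 <- make_projection_geometry(c(1, 0, 0), target = c(0, 0, 10))
  g2 <- make_projection_geometry(c(0, 1, 0), target = c(0, 0, 10))
  shots <- project_phantom(tr, g1, g2)
  tb <- triangulate_boundaries(shot_splines(shots), g1, g2)
  # boundaries parallel to the axis; their midpoint locus is the axis
  expect_lt(max(abs(tb$left[, 1] - mean(tb$left[, 1]))), 0.05)
  expect_lt(max(abs(tb$right[, 1] - mean(tb$right[, 1]))), 0.05)
  mid <- (tb$left + tb$right) / 2
  expect_lt(max(sqrt(rowSums(mid[, 1:2]^2))), 0.05)
  # swapping one view's left/right produces crossing boundaries
  sw <- shot_splines(list(A = shots$A,
                          B = list(left = shots$B$right, right = shots$B$left,
                                   fiducials_px = shots$B$fiducials_px)))
  expect_error(triangulate_boundaries(sw, g1, g2), "ordering|cross")
})

test_that("centerline extraction is exact for symmetric boundaries", {
  z <- seq(0, 30, length.out = 120)
  ba <- cbind(-1.5, 0.3, z)
  bb <- cbind(1.5, -0.3, z)
  cl <- extract_centerline(ba, bb)
  expect_lt(max(abs(cl$points[, 1])), 1e-9)
  expect_lt(max(abs(cl$points[, 2])), 1e-9)
  expect_error(extract_centerline(ba, bb[1:50, ]), "common parameter")
})

test_that("biplane pipeline recovers straight and bent centerlines", {
  # straight: sub-0.05 mm axis deviation
  tr <- cyl_truth()
  g1 <- make_projection_geometry(c(1, 0, 0), target = c(0, 0, 10))
  g2 <- make_projection_geometry(c(0, 1, 0), target = c(0, 0, 10))
  shots <- project_phantom(tr, g1, g2)
  ca <- calibrate_view(tr$fiducials, shots$A$fiducials_px)
  cb <- calibrate_view(tr$fiducials, shots$B$fiducials_px)
  tb <- triangulate_boundaries(shot_splines(shots), ca, cb)
  cl <- extract_centerline(tb$left, tb$right)
  expect_lt(max(sqrt(rowSums(cl$points[, 1:2]^2))), 0.05)

  # 60 mm arc, bend radius 50: recovered radius within 2 %, Hausdorff
  # against the true centerline under 0.1 mm
  av <- arc_views()
  arc <- arc_truth()
  ca <- calibrate_view(arc$fiducials, av$shots$A$fiducials_px)
  cb <- calibrate_view(arc$fiducials, av$shots$B$fiducials_px)
  tb <- triangulate_boundaries(shot_splines(av$shots), ca, cb)
  cl2 <- extract_centerline(tb$left, tb$right, n_samples = 300)
  fine <- centerline_at(arc$centerline, seq(0, 60, by = 0.02))$points
  expect_lt(max(nn_dist(cl2$points, fine)), 0.1)
  expect_lt(abs(fit_circle_radius(cl2$points) / 50 - 1), 0.02)
})
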