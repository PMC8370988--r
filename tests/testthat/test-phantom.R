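test_that("straight tube phantom matches closed-form geometry", {
  tr <- cyl_truth()
  # lateral area 2*pi*r*L
  expect_equal(tr$total_area_cm2 * 100, 2 * pi * 2 * 20, tolerance = 1e-6)
  # voxelized volume within 3% of pi r^2 L
  expect_lt(abs(label_volume_mm3(tr$label_volume) / (pi * 4 * 20) - 1), 0.03)
  # analytic per-slice areas constant
  expect_equal(range(tr$per_slice_lumen_area), rep(pi * 4, 2), tolerance = 1e-9)
  # centerline sampled at <= 0.2 mm
  expect_lte(max(diff(tr$centerline$arc_length)), 0.2 + 1e-9)
})

test_that("stenosis severity forces the minimum lumen area", {
  tr <- make_phantom(phantom_spec("straight", length = 50, radius = 2,
                                  stenosis = list(position = 0.5, severity = 0.5)),
                     voxel_spacing = 0.25)   # slice grid hits the stenosis center
  expect_equal(min(tr$per_slice_lumen_area), pi * 1^2, tolerance = 1e-9)
  # stenosis is local: ends keep the nominal area
  expect_equal(tr$per_slice_lumen_area[1], pi * 4, tolerance = 1e-9)
})

test_that("dissection flap creates false-lumen labels only inside its window", {
  tr <- flap_truth()
  fl_z <- which(apply(tr$label_volume$array == 2L, 3, any))
  z_mm <- (fl_z - 1) * tr$label_volume$spacing[3]
  expect_gte(min(z_mm), 8 - 0.15)
  expect_lte(max(z_mm), 14 + 0.15)
  expect_gt(tr$false_lumen_area_cm2, 0)
  # voxelized sector-shell cross-section area vs analytic oracle
  d <- tr$spec$dissection
  ang <- d$angle_deg * pi / 180
  r1 <- 2 + d$wall_offset_mm; r2 <- r1 + d$gap_mm
  a_analytic <- ang / 2 * (r2^2 - r1^2)
  k_mid <- round(11 / tr$label_volume$spacing[3]) + 1
  a_vox <- sum(tr$label_volume$array[, , k_mid] == 2L) * tr$label_volume$spacing[1]^2
  expect_lt(abs(a_vox / a_analytic - 1), 0.1)
  expect_lte(tr$false_lumen_area_cm2, tr$total_area_cm2)
})

test_that("phantom generation is deterministic for a fixed seed", {
  spec <- phantom_spec("straight", length = 10, radius = 1.5, seed = 99,
                       noise = list(detection_sigma_px = 0.3, contour_sigma_mm = 0.02))
  t1 <- make_phantom(spec, voxel_spacing = 0.3)
  t2 <- make_phantom(spec, voxel_spacing = 0.3)
  expect_identical(t1$label_volume$array, t2$label_volume$array)
  g1 <- make_projection_geometry(c(1, 0, 0), target = c(0, 0, 5))
  g2 <- make_projection_geometry(c(0, 1, 0), target = c(0, 0, 5))
  s1 <- project_phantom(t1, g1, g2, noise_px = 0.3)
  s2 <- project_phantom(t2, g1, g2, noise_px = 0.3)
  expect_identical(s1$A$fiducials_px, s2$A$fiducials_px)
  f1 <- render_oct_stack(t1, 0.5)
  f2 <- render_oct_stack(t2, 0.5)
  expect_identical(f1[[3]]$contours[[1]]$points, f2[[3]]$contours[[1]]$points)
})

test_that("voxelized lumen volume converges as spacing halves", {
  spec <- phantom_spec("straight", length = 10, radius = 1.87)
  v_true <- pi * 1.87^2 * 10
  err <- vapply(c(0.3, 0.15), function(h)
    abs(label_volume_mm3(make_phantom(spec, voxel_spacing = h)$label_volume) - v_true),
    numeric(1))
  expect_lt(err[2], err[1])
})

test_that("invalid phantom fields raise errors naming the field", {
  expect_error(phantom_spec("straight", length = -1, radius = 2), "length")
  expect_error(phantom_spec("straight", length = 10, radius = 0), "radius")
  expect_error(phantom_spec("straight", length = 10, radius = 2,
                            stenosis = list(position = 0.5, severity = 1)),
               "severity")
  expect_error(phantom_spec("straight", length = 10, radius = 2,
                            dissection = list(start_mm = 2, end_mm = 8,
                                              angle_deg = 270, gap_mm = 0.3)),
               "angle_deg")
  expect_error(phantom_spec("straight", length = 10, radius = 2,
                            dissection = list(start_mm = 8, end_mm = 2,
                                              angle_deg = 90, gap_mm = 0.3)),
               "dissection")
})

test_that("noise-free projections are exact and silhouettes are parallel bands", {
  tr <- cyl_truth()
  g1 <- make_projection_geometry(c(1, 0, 0), target = c(0, 0, 10))
  g2 <- make_projection_geometry(c(0, 1, 0), target = c(0, 0, 10))
  shots <- project_phantom(tr, g1, g2, noise_px = 0)
  expect_equal(shots$A$fiducials_px, project_points(g1, tr$fiducials),
               tolerance = 1e-12)
  # silhouette edges of a straight tube are parallel, 2r apart at the
  # detector magnification (sdd / source_distance / pixel size)
  width_px <- sqrt(rowSums((shots$A$left - shots$A$right)^2))
  mag <- 1200 / 1000 / 0.2
  expect_equal(mean(width_px), 2 * 2 * mag, tolerance = 0.01)
  expect_lt(diff(range(width_px)) / mean(width_px), 0.01)
})

test_that("views separated by 45 degrees or less trigger the acquisition warning", {
  tr <- cyl_truth()
  g1 <- make_projection_geometry(c(1, 0, 0), target = c(0, 0, 10))
  g3 <- make_projection_geometry(c(cos(pi / 6), sin(pi / 6), 0), target = c(0, 0, 10))
  expect_warning(project_phantom(tr, g1, g3), "45")
  expect_error(project_phantom(tr, g1, g1), "coincident")
})

test_that("OCT rendering covers the pullback at the requested spacing", {
  tr <- cyl_truth()
  fr <- render_oct_stack(tr, frame_spacing = 0.2)
  expect_length(fr, floor(20 / 0.2) + 1)
  # frame 0 sits at the distal end and every contour is the r = 2 circle
  expect_equal(fr[[1]]$z_mm, 0)
  r <- sqrt(rowSums(fr[[10]]$contours[[1]]$points^2))
  expect_equal(range(r), c(2, 2), tolerance = 1e-9)
  # a 75 mm pullback sampled every 0.2 mm yields 376 frames
  tr75 <- make_phantom(phantom_spec("straight", length = 75, radius = 2),
                       voxel_spacing = 0.5)
  expect_length(render_oct_stack(tr75, 0.2), 376)
  # dropout frames are flagged and carry no contours
  fr2 <- render_oct_stack(tr, 0.2, dropout = c(10, 11))
  expect_equal(fr2[[11]]$quality, "excluded")
  expect_length(fr2[[11]]$contours, 0)
  expect_error(render_oct_stack(tr, frame_spacing = 30), "length")
})
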