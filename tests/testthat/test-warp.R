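test_that("label-volume centerline is the per-slice lumen centroid", {
  tr <- cyl_truth()
  cl <- centerline_from_label(tr$label_volume)
  h <- tr$label_volume$spacing[1]
  expect_lt(max(sqrt(rowSums(cl$points[, 1:2]^2))), 0.5 * h)
  # translation equivariance: shifting the grid origin shifts the centerline
  v2 <- tr$label_volume
  v2$origin <- v2$origin + c(1, 0, 0)
  cl2 <- centerline_from_label(v2)
  expect_equal(cl2$points[, 1] - cl$points[, 1], rep(1, nrow(cl$points)),
               tolerance = 1e-9)
  # crescent cross-section: centroid matches the polygon-centroid oracle
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  outer_c <- cbind(2 * cos(th), 2 * sin(th))
  inner_c <- cbind(1 + 0.9 * cos(rev(th)), 0.9 * sin(rev(th)))
  # rasterize annulus-like crescent: outer circle minus inner disk
  fr <- list(contour_set(0, list(list(region_tag = "true_lumen", points = outer_c))),
             contour_set(1, list(list(region_tag = "true_lumen", points = outer_c))))
  vol <- contours_to_labels(fr, pixel_size = 0.05, frame_spacing = 0.2)
  inner_mask <- polygon_fill_oracle(inner_c, vol)
  arr <- vol$array
  arr[, , 1][inner_mask] <- 0L
  arr[, , 2][inner_mask] <- 0L
  vol2 <- label_volume(arr, vol$spacing, vol$origin)
  cl3 <- centerline_from_label(vol2)
  # polygon centroid oracle: area-weighted difference of the two disks
  A1 <- pi * 4; A2 <- pi * 0.81
  cx <- (A1 * 0 - A2 * 1) / (A1 - A2)
  expect_lt(abs(cl3$points[1, 1] - cx), 0.5 * 0.05)
  # empty interior slice is an error
  arr2 <- tr$label_volume$array
  arr2[, , 10] <- 0L
  expect_error(centerline_from_label(label_volume(arr2, tr$label_volume$spacing,
                                                  tr$label_volume$origin)),
               "empty slice")
})

test_that("centerline alignment recovers rigid motion and landmark maps", {
  # a helix centerline makes the rigid fit well-posed (a straight
  # centerline leaves the roll about its axis unidentifiable)
  hel <- make_phantom(phantom_spec("helix", length = 30, radius = 1,
                                   helix_radius = 8, helix_pitch = 30),
                      voxel_spacing = 1)
  cl <- hel$centerline
  al0 <- align_centerlines(cl, cl)
  expect_equal(al0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(al0$translation, rep(0, 3), tolerance = 1e-9)
  expect_equal(al0$map(7.3), 7.3, tolerance = 1e-9)

  R <- rotation_about_axis(c(1, 1, 0), 0.4)
  tv <- c(3, -2, 5)
  cl2 <- centerline(sweep(cl$points %*% t(R), 2, tv, "+"))
  al <- align_centerlines(cl, cl2)
  expect_equal(al$rotation, R, tolerance = 1e-6)
  expect_equal(al$translation, tv, tolerance = 1e-6)

  al2 <- align_centerlines(cl, cl, landmark_pairs = rbind(c(0, 0), c(30, 33)))
  expect_equal(al2$map(15), 16.5, tolerance = 1e-12)
  expect_error(align_centerlines(cl, cl, landmark_pairs = rbind(c(0, 0), c(10, 12), c(8, 15))),
               "monotone|increasing")
})

test_that("slice maps are identity for straight-to-straight and tangent-true for arcs", {
  tr <- cyl_truth()
  oct_cl <- centerline_from_label(tr$label_volume)
  sm <- build_slice_map(oct_cl, oct_cl)
  for (k in c(1, 50, length(sm$z_mm))) {
    expect_equal(sm$rotation[, , k], diag(3), tolerance = 1e-6)
  }
  expect_equal(sm$target[, 3], sm$z_mm, tolerance = 1e-6)

  arc <- make_phantom(phantom_spec("arc", length = 20, radius = 2, bend_radius = 40),
                      voxel_spacing = 1)
  sm2 <- build_slice_map(oct_cl, arc$centerline)
  s <- sm2$s_target
  tan_true <- cbind(sin(s / 40), 0, cos(s / 40))
  ang <- acos(pmin(1, rowSums(tan_true * t(sm2$rotation[, 3, ]))))
  expect_lt(max(ang) * 180 / pi, 0.1)
  # rotation-minimizing transport on a straight target adds no twist
  e1 <- t(sm$rotation[, 1, ])
  expect_lt(max(abs(sweep(e1, 2, e1[1, ]))), 1e-9)
})

test_that("forward fields match closed-form slice poses", {
  tr <- cyl_truth()
  vol <- tr$label_volume
  oct_cl <- centerline_from_label(vol)
  sm <- build_slice_map(oct_cl, oct_cl)          # identity map
  fwd <- forward_field(vol, sm)
  expect_lt(max(abs(fwd$vectors), na.rm = TRUE), 1e-6)

  # pure +5 mm axial shift
  shifted <- centerline(sweep(oct_cl$points, 2, c(0, 0, 5), "+"))
  sm2 <- build_slice_map(oct_cl, shifted)
  fwd2 <- forward_field(vol, sm2)
  expect_equal(range(fwd2$vectors[, , , 3]), c(5, 5), tolerance = 1e-6)
  expect_lt(max(abs(fwd2$vectors[, , , 1:2])), 1e-6)

  # arc bending: per-voxel displacement equals the analytic bending map
  # (slice plane rotating about the y axis, anchored at the slice's
  # lumen centroid, which is recomputed here from the raw labels)
  wc <- warp_case()
  Rb <- 40
  fwd3 <- wc$w$forward
  vol3 <- wc$truth$label_volume
  d <- dim(vol3$array)
  ax <- vol3$origin[1] + (seq_len(d[1]) - 1) * vol3$spacing[1]
  anchor_of <- function(k) {
    m <- vol3$array[, , k] > 0
    c(sum(ax * rowSums(m)), sum(ax * colSums(m))) / sum(m)
  }
  set.seed(8)
  for (rep_i in 1:20) {
    i <- sample(d[1], 1); j <- sample(d[2], 1); k <- sample(d[3], 1)
    x <- ax[i]; y <- ax[j]; z <- (k - 1) * vol3$spacing[3]
    th <- z / Rb
    anc <- anchor_of(k)
    wx <- x - anc[1]; wy <- y - anc[2]
    target <- c(Rb * (1 - cos(th)) + wx * cos(th), wy,
                Rb * sin(th) - wx * sin(th))
    u_pkg <- fwd3$vectors[i, j, k, ]
    expect_lt(max(abs(u_pkg - (target - c(x, y, z)))), 2e-3)
  }
})

test_that("field inversion satisfies the composition contract", {
  tr <- cyl_truth()
  vol <- tr$label_volume
  oct_cl <- centerline_from_label(vol)
  # constant translation: inverse is exactly the negated field
  shifted <- centerline(sweep(tr$centerline$points, 2, c(0, 0, 5), "+"))
  fwd <- forward_field(vol, build_slice_map(oct_cl, shifted))
  tg <- target_grid_for(vol, fwd)
  inv <- invert_field(fwd, tg)
  expect_equal(range(inv$vectors[, , , 3]), c(-5, -5), tolerance = 1e-6)
  expect_lt(attr(inv, "composition_residual_vox"), 0.01)

  # bending: forward-inverse composition under 0.1 voxel on lumen support
  wc <- warp_case()
  expect_lt(wc$w$composition_residual_vox, 0.1)
})

test_that("label warping preserves volume, areas and label ratios", {
  wc <- warp_case()
  vol <- wc$truth$label_volume
  warped <- wc$w$warped
  h <- vol$spacing[1]
  # rigid-motion-free bending keeps total labeled volume within 1 %
  expect_lt(abs(label_volume_mm3(warped) / label_volume_mm3(vol) - 1), 0.01)
  # per-slab cross-section area orthogonal to the target centerline
  # within 2 % away from the oblique end slabs
  pts <- label_voxel_coords(warped)
  stations <- centerline_at(wc$arc$centerline, seq(0, 30, by = 0.25))$points
  s_of <- seq(0, 30, by = 0.25)[nn_index(pts, stations)]
  slab <- cut(s_of, seq(4, 26, by = 1))
  areas <- as.numeric(table(slab)) * h^3 / 1
  expect_lt(max(abs(areas / (pi * 4) - 1)), 0.02)
  # centerline round-trip within 1 voxel over the interior
  wcl <- centerline_from_label(warped)
  fine <- centerline_at(wc$arc$centerline, seq(0, 30, by = 0.02))$points
  d <- nn_dist(wcl$points, fine)
  interior <- wcl$points[, 3] > min(wcl$points[, 3]) + 4 &
              wcl$points[, 3] < max(wcl$points[, 3]) - 4
  expect_lt(max(d[interior]), h)
})

test_that("false-lumen ratio survives warping", {
  # gentle bend: the flap sits on the inner curve, where bending
  # physically compresses volume by ~ x / bend_radius, so a tight bend
  # would change the ratio for real; at R = 300 mm that effect is well
  # below the voxel-discretization scale being tested
  tr <- flap_truth()
  arc <- make_phantom(phantom_spec("arc", length = 20, radius = 2, bend_radius = 300),
                      voxel_spacing = 1)
  w <- warp_to_centerline(tr$label_volume, arc$centerline)
  src <- label_volume_counts(tr$label_volume)
  dst <- label_volume_counts(w$warped)
  r_src <- src["false_lumen"] / (src["true_lumen"] + src["false_lumen"])
  r_dst <- dst["false_lumen"] / (dst["true_lumen"] + dst["false_lumen"])
  expect_lt(abs(r_dst / r_src - 1), 0.02)
})

test_that("tight bends below five lumen radii are rejected", {
  tr <- cyl_truth()   # r = 2, so bend radius < 10 must fail
  arc <- make_phantom(phantom_spec("arc", length = 20, radius = 2, bend_radius = 8),
                      voxel_spacing = 1)
  expect_error(warp_to_centerline(tr$label_volume, arc$centerline),
               "bend radius")
})
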