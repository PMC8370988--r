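# Shared fixtures, memoized so expensive phantoms and meshes are built
# once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# straight tube phantom r = 2 mm, L = 20 mm at the test working
# resolution (0.15 mm keeps suites fast while staying well inside the
# regime where the voxel oracles hold)
cyl_truth <- function() fixture("cyl", {
  make_phantom(phantom_spec("straight", length = 20, radius = 2, seed = 11),
               voxel_spacing = 0.2)
})

# dissected straight tube (flap: 90 deg, 0.5 mm gap over 8..14 mm)
flap_truth <- function() fixture("flap", {
  make_phantom(phantom_spec("straight", length = 20, radius = 2, seed = 12,
                            dissection = list(start_mm = 8, end_mm = 14,
                                              angle_deg = 90, gap_mm = 0.5)),
               voxel_spacing = 0.1)
})

# gentle arc phantom with well-separated oblique views
arc_truth <- function() fixture("arc", {
  make_phantom(phantom_spec("arc", length = 60, radius = 2, bend_radius = 50,
                            seed = 13), voxel_spacing = 0.2)
})

arc_views <- function() fixture("arc_views", {
  tr <- arc_truth()
  ctr <- colMeans(tr$centerline$points)
  ga <- make_projection_geometry(c(0, 1, 0), target = ctr)
  gb <- make_projection_geometry(c(0.9, 0.3, 0.3), target = ctr)
  shots <- project_phantom(tr, ga, gb, noise_px = 0)
  list(ga = ga, gb = gb, shots = shots)
})

# four boundary splines from a projected phantom shot pair
shot_splines <- function(shots) {
  list(boundary_spline(shots$A$left, "left", "A"),
       boundary_spline(shots$A$right, "right", "A"),
       boundary_spline(shots$B$left, "left", "B"),
       boundary_spline(shots$B$right, "right", "B"))
}

# cylinder surface mesh at the test resolution
cyl_mesh <- function() fixture("cyl_mesh", label_to_surface(cyl_truth()$label_volume))

# short fine cylinder (h = 0.12) for metric accuracy checks
cyl12_truth <- function() fixture("cyl12", {
  make_phantom(phantom_spec("straight", length = 10, radius = 2, seed = 16),
               voxel_spacing = 0.12)
})
cyl12_mesh <- function() fixture("cyl12_mesh", label_to_surface(cyl12_truth()$label_volume))
cyl12_clipped <- function() fixture("cyl12_clipped", {
  clip_and_extend(cyl12_mesh(), cyl12_truth()$centerline, 1.5, 8.5, ext_len = 0)
})

flap_mesh <- function() fixture("flap_mesh", label_to_surface(flap_truth()$label_volume))

# clipped + extended cylinder mesh
cyl_clipped <- function() fixture("cyl_clipped", {
  tr <- cyl_truth()
  clip_and_extend(cyl_mesh(), tr$centerline, 2, 18, ext_len = 6)
})

# straight-to-arc warp of a short cylinder (shared by warp tests and
# the geometry acceptance check)
warp_case <- function() fixture("warp_case", {
  tr <- make_phantom(phantom_spec("straight", length = 30, radius = 2, seed = 14),
                     voxel_spacing = 0.15)
  arc <- make_phantom(phantom_spec("arc", length = 30, radius = 2,
                                   bend_radius = 40, seed = 15),
                      voxel_spacing = 1)
  w <- warp_to_centerline(tr$label_volume, arc$centerline)
  list(truth = tr, arc = arc, w = w)
})

# independent point-in-polygon oracle (winding-angle summation; the
# package itself uses even-odd scanline filling)
polygon_fill_oracle <- function(poly, vol) {
  d <- dim(vol$array)
  ax <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  ay <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  X <- matrix(ax, d[1], d[2])
  Y <- matrix(ay, d[1], d[2], byrow = TRUE)
  wind <- matrix(0, d[1], d[2])
  m <- nrow(poly)
  for (i in seq_len(m)) {
    j <- if (i == m) 1 else i + 1
    a1 <- atan2(poly[i, 2] - Y, poly[i, 1] - X)
    a2 <- atan2(poly[j, 2] - Y, poly[j, 1] - X)
    da <- a2 - a1
    da[da > pi] <- da[da > pi] - 2 * pi
    da[da < -pi] <- da[da < -pi] + 2 * pi
    wind <- wind + da
  }
  abs(wind) > pi
}

# simple closed circle contour (m x 2, not repeating the first point)
circle_contour <- function(r, n = 120, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}
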