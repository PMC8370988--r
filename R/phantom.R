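#' Specification of a synthetic vessel phantom
#'
#' Phantoms stand in for patient anatomy so that every reconstruction
#' stage can be verified against known ground truth.  A phantom is a
#' tube swept along an analytic centerline with an arc-length radius
#' profile, optionally narrowed by a smooth stenosis and carrying a
#' dissection flap: a circumferential shell separated from the wall by
#' a uniform radial gap, which creates a false lumen of quantifiable
#' area (mimicking the intimal tears seen after balloon angioplasty).
#'
#' @param centerline_kind one of `"straight"`, `"arc"`, `"helix"`,
#'   `"spline"`.
#' @param length vessel length in mm (> 0).
#' @param radius lumen radius in mm: a scalar or a function of arc
#'   length (mm) returning mm (> 0 everywhere).
#' @param stenosis optional list `(position, severity, width_mm)`:
#'   `position` is the center as a fraction of length in \[0, 1\],
#'   `severity` the fractional radius reduction in \[0, 1), and
#'   `width_mm` the full width of the cosine-squared narrowing
#'   (default 10 mm).
#' @param dissection optional list `(start_mm, end_mm, angle_deg,
#'   gap_mm, wall_offset_mm)`: arc-length window of the flap, angular
#'   extent in (0, 180\] degrees, radial gap of the false lumen, and
#'   flap thickness separating it from the true lumen (default
#'   0.3 mm, a typical intimal flap scale and several working voxels
#'   so the flap survives voxelization).
#' @param bend_radius bend radius in mm for `"arc"` centerlines
#'   (default 100).
#' @param helix_radius,helix_pitch helix geometry in mm for `"helix"`
#'   (defaults 10 and 50).
#' @param control_points n x 3 matrix for `"spline"` centerlines.
#' @param fiducials n x 3 matrix of radiopaque marker positions in mm
#'   (>= 8, non-coplanar); defaults to [default_fiducials()].
#' @param noise list `(detection_sigma_px, contour_sigma_mm)` used by
#'   the projection and OCT renderers (defaults 0, 0).
#' @param seed integer seed making all phantom-derived noise
#'   reproducible.
#' @return object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec("straight", length = 50, radius = 2)
phantom_spec <- function(centerline_kind = c("straight", "arc", "helix", "spline"),
                         length, radius,
                         stenosis = NULL, dissection = NULL,
                         bend_radius = 100, helix_radius = 10, helix_pitch = 50,
                         control_points = NULL,
                         fiducials = NULL,
                         noise = list(detection_sigma_px = 0, contour_sigma_mm = 0),
                         seed = 1L) {
  centerline_kind <- match.arg(centerline_kind)
  if (!is.numeric(length) || length <= 0) stop("invalid phantom field 'length': must be > 0")
  if (is.numeric(radius)) {
    r0 <- radius
    if (r0 <= 0) stop("invalid phantom field 'radius': must be > 0")
    radius <- function(s) rep_len(r0, base::length(s))
  } else if (!is.function(radius)) {
    stop("invalid phantom field 'radius': scalar or function of arc length")
  }
  if (!is.null(stenosis)) {
    stenosis <- modifyList(list(width_mm = 10), stenosis)
    if (is.null(stenosis$position) || stenosis$position < 0 || stenosis$position > 1)
      stop("invalid phantom field 'stenosis$position': fraction in [0, 1]")
    if (is.null(stenosis$severity) || stenosis$severity < 0 || stenosis$severity >= 1)
      stop("invalid phantom field 'stenosis$severity': fraction in [0, 1)")
  }
  if (!is.null(dissection)) {
    dissection <- modifyList(list(wall_offset_mm = 0.3), dissection)
    if (is.null(dissection$start_mm) || is.null(dissection$end_mm) ||
        dissection$start_mm < 0 || dissection$end_mm > length ||
        dissection$start_mm >= dissection$end_mm)
      stop("invalid phantom field 'dissection': need 0 <= start_mm < end_mm <= length")
    if (is.null(dissection$angle_deg) || dissection$angle_deg <= 0 || dissection$angle_deg > 180)
      stop("invalid phantom field 'dissection$angle_deg': must be in (0, 180]")
    if (is.null(dissection$gap_mm) || dissection$gap_mm <= 0)
      stop("invalid phantom field 'dissection$gap_mm': must be > 0")
  }
  if (centerline_kind == "spline") {
    if (is.null(control_points) || nrow(control_points) < 4)
      stop("invalid phantom field 'control_points': spline needs >= 4 points")
  }
  if (is.null(fiducials)) fiducials <- default_fiducials(length)
  fiducials <- as.matrix(fiducials)
  if (nrow(fiducials) < 8) stop("invalid phantom field 'fiducials': need >= 8 markers")
  noise <- modifyList(list(detection_sigma_px = 0, contour_sigma_mm = 0), noise)

  # validate the radius over the full length (including stenosis)
  s_chk <- seq(0, length, length.out = 512)
  r_chk <- .effective_radius(radius, stenosis, length)(s_chk)
  if (any(!is.finite(r_chk)) || any(r_chk <= 0))
    stop("invalid phantom field 'radius': must be finite and > 0 everywhere")

  structure(list(centerline_kind = centerline_kind, length = length,
                 radius = radius, stenosis = stenosis, dissection = dissection,
                 bend_radius = bend_radius, helix_radius = helix_radius,
                 helix_pitch = helix_pitch, control_points = control_points,
                 fiducials = fiducials, noise = noise, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Radius profile with the stenosis applied (cosine-squared narrowing
# reaching (1 - severity) * radius at the stenosis center).
.effective_radius <- function(radius_fun, stenosis, length) {
  force(radius_fun); force(stenosis); force(length)
  function(s) {
    r <- radius_fun(s)
    if (!is.null(stenosis)) {
      sc <- stenosis$position * length
      w <- stenosis$width_mm
      inside <- abs(s - sc) <= w / 2
      fac <- rep(1, base::length(s))
      fac[inside] <- 1 - stenosis$severity * cos(pi * (s[inside] - sc) / w)^2
      r <- r * fac
    }
    r
  }
}

#' Default non-coplanar fiducial layout
#'
#' Sixteen markers on two coaxial square frames bracketing the vessel
#' plus four mid-plane offset markers, guaranteeing a non-degenerate
#' configuration for DLT calibration.
#'
#' @param length vessel length in mm.
#' @param half_width lateral half-extent of the marker frame in mm.
#' @return 16 x 3 matrix of marker positions (mm).
#' @export
default_fiducials <- function(length, half_width = 40) {
  h <- half_width
  z <- c(-5, length + 5)
  ring <- rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h))
  frames <- do.call(rbind, lapply(z, function(zz) cbind(ring, zz)))
  mid <- rbind(c(-h, 0, length * 0.25), c(h, 0, length * 0.4),
               c(0, -h, length * 0.6), c(0, h, length * 0.75))
  skew <- rbind(c(-h / 2, h / 3, length * 0.1), c(h / 3, -h / 2, length * 0.55),
                c(h / 2, h / 2, length * 0.35), c(-h / 3, -h / 3, length * 0.85))
  rbind(frames, mid, skew)
}

# Analytic centerline sample for a phantom spec at arc lengths s
.phantom_centerline_points <- function(spec, s) {
  switch(spec$centerline_kind,
    straight = cbind(0, 0, s),
    arc = {
      R <- spec$bend_radius
      cbind(R * (1 - cos(s / R)), 0, R * sin(s / R))
    },
    helix = {
      a <- spec$helix_radius
      b <- spec$helix_pitch / (2 * pi)
      c0 <- sqrt(a^2 + b^2)
      u <- s / c0
      cbind(a * (cos(u) - 1), a * sin(u), b * u)
    },
    spline = {
      cp <- spec$control_points
      t_cp <- polyline_arclength(cp)
      fine <- seq(0, max(t_cp), length.out = 2048)
      pts <- vapply(1:3, function(j)
        predict(smooth.spline(t_cp, cp[, j], spar = 0.2), fine)$y,
        numeric(length(fine)))
      s_fine <- polyline_arclength(pts)
      polyline_at(pts, s_fine, s * max(s_fine) / max(s))
    })
}

#' Build a synthetic vessel phantom with analytic ground truth
#'
#' Samples the analytic centerline, voxelizes the straightened lumen
#' (true and false) on a regular grid, and records analytic surface
#' areas and per-slice lumen areas for downstream verification.
#'
#' @param spec a [phantom_spec].
#' @param voxel_spacing isotropic voxel size of the straightened truth
#'   label volume in mm (default 0.075, the working resolution of the
#'   reconstruction pipeline).
#' @param centerline_ds centerline sampling interval in mm (<= 0.2).
#' @param margin_mm in-plane padding of the label grid beyond the
#'   largest lumen radius (default 1 mm).
#' @return object of class `phantom_truth`: list with `spec`,
#'   `centerline` (anatomical space), `radius` (effective radius
#'   function of arc length, mm), `label_volume` (straightened),
#'   `per_slice_lumen_area` (mm^2, analytic, one per slice),
#'   `total_area_cm2` and `false_lumen_area_cm2` (analytic lateral
#'   areas), and `fiducials`.
#' @export
#' @examples
#' tr <- make_phantom(phantom_spec("straight", length = 20, radius = 2),
#'                    voxel_spacing = 0.3)
#' tr$total_area_cm2 * 100 # lateral area in mm^2
make_phantom <- function(spec, voxel_spacing = 0.075, centerline_ds = 0.2,
                         margin_mm = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (centerline_ds > 0.2) centerline_ds <- 0.2
  L <- spec$length
  s <- seq(0, L, by = centerline_ds)
  if (max(s) < L) s <- c(s, L)
  cl <- centerline(.phantom_centerline_points(spec, s))
  r_fun <- .effective_radius(spec$radius, spec$stenosis, L)

  # --- straightened label volume ---
  r_max <- max(r_fun(seq(0, L, length.out = 1024)))
  d <- spec$dissection
  r_out <- r_max + if (!is.null(d)) d$wall_offset_mm + d$gap_mm else 0
  half <- r_out + margin_mm
  nxy <- ceiling(2 * half / voxel_spacing) + 1
  nz <- floor(L / voxel_spacing) + 1
  ax <- (seq_len(nxy) - 1) * voxel_spacing - half
  xg <- matrix(ax, nxy, nxy)
  yg <- t(xg)
  rho <- sqrt(xg^2 + yg^2)
  theta <- atan2(yg, xg)
  arr <- array(0L, c(nxy, nxy, nz))
  z_s <- (seq_len(nz) - 1) * voxel_spacing
  r_z <- r_fun(z_s)
  ang <- if (!is.null(d)) d$angle_deg * pi / 180 else NULL
  for (k in seq_len(nz)) {
    sl <- matrix(0L, nxy, nxy)
    sl[rho <= r_z[k]] <- 1L
    if (!is.null(d) && z_s[k] >= d$start_mm && z_s[k] <= d$end_mm) {
      r1 <- r_z[k] + d$wall_offset_mm
      r2 <- r1 + d$gap_mm
      in_sector <- rho >= r1 & rho <= r2 & theta >= -ang / 2 & theta <= ang / 2
      sl[in_sector] <- 2L
    }
    arr[, , k] <- sl
  }
  vol <- label_volume(arr, spacing = rep(voxel_spacing, 3),
                      origin = c(-half, -half, 0))

  # --- analytic areas ---
  s_f <- seq(0, L, length.out = 4096)
  r_f <- r_fun(s_f)
  dr <- c(diff(r_f) / diff(s_f), 0)
  lateral <- trapz_xy(s_f, 2 * pi * r_f * sqrt(1 + dr^2))
  fl_area <- 0
  if (!is.null(d)) {
    in_fl <- s_f >= d$start_mm & s_f <= d$end_mm
    r1 <- r_f + d$wall_offset_mm
    r2 <- r1 + d$gap_mm
    Lf <- d$end_mm - d$start_mm
    # inner + outer sector shells, two radial side walls, two end walls
    shells <- trapz_xy(s_f[in_fl], ang * (r1[in_fl] + r2[in_fl]))
    sides <- 2 * d$gap_mm * Lf
    r1e <- r_fun(c(d$start_mm, d$end_mm)) + d$wall_offset_mm
    ends <- sum(ang / 2 * ((r1e + d$gap_mm)^2 - r1e^2))
    fl_area <- shells + sides + ends
  }
  per_slice <- pi * r_z^2
  if (!is.null(d)) {
    in_fl <- z_s >= d$start_mm & z_s <= d$end_mm
    r1 <- r_z[in_fl] + d$wall_offset_mm
    per_slice[in_fl] <- per_slice[in_fl] + ang / 2 * ((r1 + d$gap_mm)^2 - r1^2)
  }

  structure(list(spec = spec, centerline = cl, radius = r_fun,
                 label_volume = vol, per_slice_lumen_area = per_slice,
                 slice_arc = z_s,
                 total_area_cm2 = (lateral + fl_area) / 100,
                 false_lumen_area_cm2 = fl_area / 100,
                 fiducials = spec$fiducials),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s, L = %.1f mm, total area %.3f cm^2 (false lumen %.3f cm^2)\n",
              x$spec$centerline_kind, x$spec$length,
              x$total_area_cm2, x$false_lumen_area_cm2))
  invisible(x)
}

# trapezoidal rule on an irregular grid
trapz_xy <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Render biplane projections of a phantom
#'
#' Projects the fiducial markers and the lumen silhouette of a phantom
#' through two pinhole projection geometries, emulating the calibrated
#' biplane X-ray acquisition.  The silhouette of the swept tube is
#' computed by projecting the centerline offset by the local radius
#' along the direction orthogonal to both the viewing ray and the
#' centerline tangent (exact for parallel rays; the residual
#' perspective error is O(r^2 / source distance)).  Views separated by
#' 45 degrees or less trigger a warning mirroring the > 45 degree
#' acquisition rule for biplane angiography.
#'
#' @param truth a [phantom_truth].
#' @param geom_a,geom_b [projection_geometry] objects for the two views.
#' @param noise_px standard deviation (px) of Gaussian detection noise
#'   added to fiducial projections.
#' @param n_boundary number of silhouette samples per edge.
#' @param seed RNG seed for the detection noise; defaults to the
#'   phantom seed plus one so that a phantom renders identically on
#'   every call.
#' @return list with one element per view (`A`, `B`), each containing
#'   `fiducials_px` (n x 2), `left`/`right` silhouette point matrices
#'   (px) ordered proximal to distal by normalized arc length `param`.
#' @export
project_phantom <- function(truth, geom_a, geom_b, noise_px = 0,
                            n_boundary = 200, seed = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  va <- view_axis(geom_a); vb <- view_axis(geom_b)
  sep <- acos(pmin(1, abs(sum(va * vb)))) * 180 / pi
  if (sep < 1e-6) stop("degenerate biplane geometry: coincident view axes")
  if (sep <= 45)
    warning(sprintf(
      "view separation %.1f deg <= 45 deg; biplane acquisitions should be separated by > 45 deg",
      sep))
  if (is.null(seed)) seed <- truth$spec$seed + 1L
  set.seed(seed)

  s_par <- seq(0, 1, length.out = n_boundary)
  s_mm <- s_par * centerline_length(truth$centerline)
  ca <- centerline_at(truth$centerline, s_mm)
  r_mm <- truth$radius(s_mm)

  one_view <- function(geom) {
    det <- project_points(geom, truth$fiducials)
    if (noise_px > 0)
      det <- det + matrix(stats::rnorm(length(det), 0, noise_px), ncol = 2)
    axis <- view_axis(geom)
    n <- nrow(ca$points)
    left <- matrix(0, n, 3); right <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      e <- cross3(axis, ca$tangent[i, ])
      if (vnorm(e) < 1e-9) e <- ca$normal[i, ] # tangent parallel to view axis
      e <- unitv(e)
      left[i, ] <- ca$points[i, ] - r_mm[i] * e
      right[i, ] <- ca$points[i, ] + r_mm[i] * e
    }
    sig <- truth$spec$noise$contour_sigma_mm
    if (sig > 0) {
      left <- left + matrix(stats::rnorm(3 * n, 0, sig), n, 3)
      right <- right + matrix(stats::rnorm(3 * n, 0, sig), n, 3)
    }
    list(fiducials_px = det,
         left = project_points(geom, left),
         right = project_points(geom, right),
         param = s_par)
  }
  list(A = one_view(geom_a), B = one_view(geom_b))
}

#' Render a phantom as an OCT-like contour stack
#'
#' Cross-sections orthogonal to the true centerline are sampled at a
#' uniform arc-length spacing, starting at the distal end (frame 0),
#' mirroring a motorized OCT pullback.  Each frame carries the true
#' lumen contour and, within the dissection window, a separate
#' false-lumen contour.  Frames listed in `dropout` are flagged
#' `excluded` and carry no contours, emulating the clinical exclusion
#' of frames with insufficient blood clearing.
#'
#' @param truth a [phantom_truth].
#' @param frame_spacing pullback frame interval in mm.
#' @param pixel_size nominal in-plane pixel size in mm (recorded on the
#'   frames; contours themselves are continuous).
#' @param dropout integer vector of 0-based frame indices to exclude.
#' @param n_points number of polygon vertices per contour.
#' @param seed RNG seed for contour noise; defaults to phantom seed + 2.
#' @return list of `contour_set` objects (see [contour_set]).
#' @export
render_oct_stack <- function(truth, frame_spacing, pixel_size = 0.0102,
                             dropout = integer(0), n_points = 180,
                             seed = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  L <- truth$spec$length
  if (frame_spacing <= 0) stop("frame_spacing must be > 0")
  if (frame_spacing > L) stop("frame_spacing exceeds the phantom length")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (is.null(seed)) seed <- truth$spec$seed + 2L
  set.seed(seed)

  n_frames <- floor(L / frame_spacing) + 1
  d <- truth$spec$dissection
  sig <- truth$spec$noise$contour_sigma_mm
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  lapply(seq_len(n_frames) - 1L, function(k) {
    if (k %in% dropout)
      return(contour_set(k, list(), quality = "excluded",
                         z_mm = k * frame_spacing, pixel_size = pixel_size))
    s_k <- k * frame_spacing
    r_k <- truth$radius(s_k)
    r_pts <- r_k + if (sig > 0) stats::rnorm(n_points, 0, sig) else 0
    contours <- list(list(region_tag = "true_lumen",
                          points = cbind(r_pts * cos(th), r_pts * sin(th))))
    if (!is.null(d) && s_k >= d$start_mm && s_k <= d$end_mm) {
      ang <- d$angle_deg * pi / 180
      r1 <- r_k + d$wall_offset_mm
      r2 <- r1 + d$gap_mm
      a_seq <- seq(-ang / 2, ang / 2, length.out = max(24, ceiling(n_points * ang / (2 * pi))))
      poly <- rbind(cbind(r1 * cos(a_seq), r1 * sin(a_seq)),
                    cbind(r2 * cos(rev(a_seq)), r2 * sin(rev(a_seq))))
      if (sig > 0) poly <- poly + matrix(stats::rnorm(length(poly), 0, sig / 2), ncol = 2)
      contours <- c(contours, list(list(region_tag = "false_lumen", points = poly)))
    }
    contour_set(k, contours, quality = "ok", z_mm = s_k, pixel_size = pixel_size)
  })
}
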