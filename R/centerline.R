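#' Arterial centerline with rotation-minimizing frames
#'
#' A centerline is an ordered 3D polyline with cumulative arc length and
#' a per-sample orthonormal triad (tangent, normal, binormal).  The
#' normal/binormal pair is propagated by rotation-minimizing (double
#' reflection) transport rather than Frenet frames, which degenerate at
#' inflection points of near-straight arteries.
#'
#' @param points numeric matrix (n x 3), ordered samples in mm.
#' @param ref_normal optional unit vector seeding the in-plane frame at
#'   the first sample; it is projected orthogonal to the first tangent.
#'   Defaults to the axis least aligned with the first tangent.
#' @return An object of class `centerline`: a list with `points`
#'   (n x 3), `arc_length` (n, mm, strictly increasing), `tangent`,
#'   `normal`, `binormal` (each n x 3, orthonormal per row-triple).
#' @export
#' @examples
#' z <- seq(0, 50, by = 0.5)
#' cl <- centerline(cbind(0, 0, z))
#' range(cl$arc_length)
centerline <- function(points, ref_normal = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 2)
    stop("centerline requires an n x 3 matrix with n >= 2")
  s <- polyline_arclength(points)
  keep <- c(TRUE, diff(s) > 1e-12)
  points <- points[keep, , drop = FALSE]
  s <- polyline_arclength(points)
  if (nrow(points) < 2) stop("centerline has no extent")

  tang <- central_diff_tangents(points)
  fr <- rmf_transport(points, tang, ref_normal)

  structure(
    list(points = points, arc_length = s, tangent = tang,
         normal = fr$normal, binormal = fr$binormal),
    class = "centerline"
  )
}

# Central-difference unit tangents at polyline samples; second-order
# one-sided stencils at the two ends (a first-order end tangent tilts
# the end slice poses by O(h / bend radius))
central_diff_tangents <- function(pts) {
  n <- nrow(pts)
  if (n == 2) return(row_unit(rbind(pts[2, ] - pts[1, ], pts[2, ] - pts[1, ])))
  d <- rbind(-3 * pts[1, ] + 4 * pts[2, ] - pts[3, ],
             pts[seq(3, n), , drop = FALSE] - pts[seq(1, n - 2), , drop = FALSE],
             3 * pts[n, ] - 4 * pts[n - 1, ] + pts[n - 2, ])
  row_unit(d)
}

# Rotation-minimizing frame propagation by the double-reflection method
# (Wang et al. 2008).  Exact for rigid transport on straight segments.
rmf_transport <- function(pts, tang, ref_normal = NULL) {
  n <- nrow(pts)
  normal <- matrix(0, n, 3)
  binorm <- matrix(0, n, 3)
  t0 <- tang[1, ]
  if (is.null(ref_normal)) {
    ref <- diag(3)[, which.min(abs(t0))]
  } else {
    ref <- ref_normal
  }
  r0 <- ref - sum(ref * t0) * t0
  if (vnorm(r0) < 1e-9)
    stop("reference normal is parallel to the initial tangent")
  normal[1, ] <- unitv(r0)
  binorm[1, ] <- cross3(t0, normal[1, ])
  for (i in seq_len(n - 1)) {
    v1 <- pts[i + 1, ] - pts[i, ]
    c1 <- sum(v1 * v1)
    rL <- normal[i, ] - (2 / c1) * sum(v1 * normal[i, ]) * v1
    tL <- tang[i, ] - (2 / c1) * sum(v1 * tang[i, ]) * v1
    v2 <- tang[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    r2 <- if (c2 < 1e-30) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthonormalize against the true tangent to kill drift
    r2 <- r2 - sum(r2 * tang[i + 1, ]) * tang[i + 1, ]
    normal[i + 1, ] <- unitv(r2)
    binorm[i + 1, ] <- cross3(tang[i + 1, ], normal[i + 1, ])
  }
  list(normal = normal, binormal = binorm)
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d samples, length %.2f mm\n",
              nrow(x$points), max(x$arc_length)))
  invisible(x)
}

#' Total arc length of a centerline (mm)
#' @param cl a [centerline].
#' @return scalar length in mm.
#' @export
centerline_length <- function(cl) max(cl$arc_length)

#' Evaluate a centerline at arbitrary arc-length stations
#'
#' Positions are interpolated linearly between samples; the frame is
#' taken from linear interpolation of the sampled triad followed by
#' re-orthonormalization (Gram-Schmidt against the interpolated
#' tangent), which preserves the rotation-minimizing character away
#' from sampling-scale features.
#'
#' @param cl a [centerline].
#' @param s numeric vector of arc lengths (mm); clamped to the
#'   centerline range.
#' @return list with `points` (m x 3), `tangent`, `normal`, `binormal`.
#' @export
centerline_at <- function(cl, s) {
  s <- pmin(pmax(s, min(cl$arc_length)), max(cl$arc_length))
  p <- polyline_at(cl$points, cl$arc_length, s)
  tg <- polyline_at(cl$tangent, cl$arc_length, s)
  nm <- polyline_at(cl$normal, cl$arc_length, s)
  m <- length(s)
  tangent <- matrix(0, m, 3); normal <- matrix(0, m, 3); binormal <- matrix(0, m, 3)
  for (i in seq_len(m)) {
    t_i <- unitv(tg[i, ])
    n_i <- nm[i, ] - sum(nm[i, ] * t_i) * t_i
    n_i <- unitv(n_i)
    tangent[i, ] <- t_i
    normal[i, ] <- n_i
    binormal[i, ] <- cross3(t_i, n_i)
  }
  list(points = p, tangent = tangent, normal = normal, binormal = binormal)
}

#' Write a centerline to CSV (s_mm, x, y, z, frame components)
#' @param cl a [centerline].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_centerline_csv <- function(cl, path) {
  df <- data.frame(
    s_mm = cl$arc_length,
    x = cl$points[, 1], y = cl$points[, 2], z = cl$points[, 3],
    tx = cl$tangent[, 1], ty = cl$tangent[, 2], tz = cl$tangent[, 3],
    nx = cl$normal[, 1], ny = cl$normal[, 2], nz = cl$normal[, 3],
    bx = cl$binormal[, 1], by = cl$binormal[, 2], bz = cl$binormal[, 3]
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a centerline from the CSV layout written by [write_centerline_csv]
#' @param path CSV file.
#' @return a [centerline].
#' @export
read_centerline_csv <- function(path) {
  df <- read.csv(path)
  centerline(as.matrix(df[, c("x", "y", "z")]))
}

#' Write a centerline as a legacy-VTK polyline
#' @param cl a [centerline].
#' @param path output `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_centerline_vtk <- function(cl, path) {
  n <- nrow(cl$points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "centerline", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", n)), con)
  writeLines(apply(cl$points, 1, function(p) paste(format(p, digits = 9), collapse = " ")), con)
  writeLines(sprintf("LINES 1 %d", n + 1), con)
  writeLines(paste(c(n, seq_len(n) - 1L), collapse = " "), con)
  invisible(path)
}
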