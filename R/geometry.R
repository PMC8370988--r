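# Low-level vector geometry used throughout: unit vectors, cross
# products, axis-angle rotations, polyline arc length, nearest-point
# queries.  All coordinates are world millimetres, right-handed.

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rows of a matrix normalized to unit length
row_unit <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}

#' Rotation matrix about an axis (Rodrigues form)
#' @param axis rotation axis (any nonzero 3-vector).
#' @param angle angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- unitv(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Minimal rotation carrying unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  c_ab <- sum(a * b)
  if (c_ab > 1 - 1e-14) return(diag(3))
  if (c_ab < -1 + 1e-12) {
    # 180 degrees: rotate about any axis orthogonal to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unitv(cross3(a, ref))
    return(rotation_about_axis(axis, pi))
  }
  v <- cross3(a, b)
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + (K %*% K) / (1 + c_ab)
}

# Cumulative arc length of an ordered polyline (n x d matrix)
polyline_arclength <- function(pts) {
  if (nrow(pts) < 2) return(rep(0, nrow(pts)))
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# Resample a polyline at prescribed arc-length stations (linear)
polyline_at <- function(pts, s, s_query) {
  out <- vapply(seq_len(ncol(pts)), function(j) {
    approx(s, pts[, j], xout = s_query, rule = 2)$y
  }, numeric(length(s_query)))
  matrix(out, nrow = length(s_query), ncol = ncol(pts))
}

#' Directed nearest-neighbor distances between point sets
#' @param a,b point matrices (rows are points).
#' @param chunk rows of `a` processed per block (bounds memory).
#' @return distance from each row of `a` to its nearest row of `b`.
#' @export
nn_dist <- function(a, b, chunk = 2000L) {
  out <- numeric(nrow(a))
  bb <- rowSums(b^2)
  for (i0 in seq(1L, nrow(a), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nrow(a))
    aa <- a[idx, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), bb, "+") - 2 * aa %*% t(b)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Symmetric Hausdorff distance between two point sets
#' @param a,b point matrices (rows are points).
#' @return the Hausdorff distance (same units as the coordinates).
#' @export
hausdorff_dist <- function(a, b) {
  max(max(nn_dist(a, b)), max(nn_dist(b, a)))
}

#' Least-squares circle radius of a near-planar point set
#'
#' Projects the points on their first two principal axes and fits a
#' circle algebraically (Kasa fit); used to verify recovered bend
#' radii against phantom ground truth.
#'
#' @param pts n x 3 (or n x 2) point matrix.
#' @return fitted radius.
#' @export
fit_circle_radius <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x)
  uv <- x %*% sv$v[, 1:2]
  A <- cbind(2 * uv[, 1], 2 * uv[, 2], 1)
  b <- uv[, 1]^2 + uv[, 2]^2
  sol <- qr.solve(A, b)
  sqrt(sol[3] + sol[1]^2 + sol[2]^2)
}
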