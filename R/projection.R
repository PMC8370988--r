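#' Pinhole projection geometry of an X-ray view
#'
#' Wraps a 3 x 4 homogeneous projection matrix mapping world mm to
#' image px, together with the calibration reprojection error.
#'
#' @param P 3 x 4 projection matrix of rank 3.
#' @param reprojection_rms calibration reprojection RMS in px.
#' @return object of class `projection_geometry`.
#' @export
projection_geometry <- function(P, reprojection_rms = 0) {
  P <- as.matrix(P)
  if (!all(dim(P) == c(3, 4))) stop("projection matrix must be 3 x 4")
  if (qr(P)$rank < 3) stop("projection matrix must have rank 3")
  if (reprojection_rms < 0) stop("reprojection_rms must be >= 0")
  structure(list(P = P, reprojection_rms = reprojection_rms),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("<projection_geometry> reprojection RMS %.3g px\n", x$reprojection_rms))
  invisible(x)
}

#' Build an ideal pinhole (cone-beam) geometry
#'
#' Constructs the projection matrix of a source looking at `target`
#' along `view_dir`, with the detector orthogonal to the view axis.
#'
#' @param view_dir unit (or any nonzero) vector from source towards the
#'   scene.
#' @param target world point (mm) the view is centered on.
#' @param source_distance source-to-target distance in mm.
#' @param sdd source-to-detector distance in mm.
#' @param pixel_mm detector pixel pitch in mm.
#' @param principal_point image coordinates (px) of the view axis.
#' @param up approximate detector up direction.
#' @return a [projection_geometry].
#' @export
#' @examples
#' g <- make_projection_geometry(c(1, 0, 0), target = c(0, 0, 25))
make_projection_geometry <- function(view_dir, target = c(0, 0, 0),
                                     source_distance = 1000, sdd = 1200,
                                     pixel_mm = 0.2,
                                     principal_point = c(512, 512),
                                     up = c(0, 0, 1)) {
  w <- unitv(view_dir)                       # camera z: points into the scene
  u <- up - sum(up * w) * w
  if (vnorm(u) < 1e-9) u <- c(0, 1, 0) - sum(c(0, 1, 0) * w) * w
  v <- unitv(u)
  u <- cross3(v, w)                          # right-handed (u, v, w)
  R <- rbind(u, v, w)
  C <- target - source_distance * w
  f <- sdd / pixel_mm
  K <- matrix(c(f, 0, 0, 0, f, 0, principal_point[1], principal_point[2], 1), 3, 3)
  P <- K %*% cbind(R, -R %*% C)
  projection_geometry(P)
}

#' Project world points through a projection geometry
#' @param geom a [projection_geometry].
#' @param X n x 3 matrix of world points (mm).
#' @return n x 2 matrix of image points (px).
#' @export
project_points <- function(geom, X) {
  X <- rbind(t(as.matrix(X)), 1)
  x <- geom$P %*% X
  t(x[1:2, , drop = FALSE] / rep(x[3, ], each = 2))
}

# Principal (viewing) axis of a projection geometry: the direction of
# increasing depth, sign-fixed by det(M) so it points into the scene.
view_axis <- function(geom) {
  M <- geom$P[, 1:3]
  unitv(sign(det(M)) * M[3, ])
}

# Camera center (world mm): right null space of P
camera_center <- function(geom) {
  M <- geom$P[, 1:3]
  as.numeric(-solve(M, geom$P[, 4]))
}

# Unit ray direction through pixel (u, v), pointing into the scene
backproject_ray <- function(geom, uv) {
  M <- geom$P[, 1:3]
  d <- solve(M, c(uv, 1))
  unitv(sign(det(M)) * d)
}
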