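#' Calibrate an X-ray view from fiducial correspondences (DLT)
#'
#' Recovers the 3 x 4 projection matrix of a view by the direct linear
#' transform: each correspondence between a radiopaque fiducial of
#' known 3D position and its 2D detection contributes two homogeneous
#' equations, and the least-squares solution is the smallest right
#' singular vector of the stacked system.  Points are Hartley-
#' normalized before solving for numerical conditioning.
#'
#' @param fiducials_3d n x 3 matrix of marker positions (mm), n >= 6,
#'   non-coplanar.
#' @param detections_2d n x 2 matrix of detected marker centroids (px).
#' @return a [projection_geometry] carrying the reprojection RMS (px).
#' @export
#' @examples
#' g0 <- make_projection_geometry(c(1, 0, 0), target = c(0, 0, 25))
#' F <- default_fiducials(50)
#' g <- calibrate_view(F, project_points(g0, F))
#' g$reprojection_rms
calibrate_view <- function(fiducials_3d, detections_2d) {
  X <- as.matrix(fiducials_3d)
  x <- as.matrix(detections_2d)
  n <- nrow(X)
  if (n < 6 || nrow(x) != n)
    stop("underdetermined calibration: need >= 6 point correspondences")
  ctr <- colMeans(X)
  sv <- svd(sweep(X, 2, ctr))$d
  if (sv[3] < 1e-6 * sv[1])
    stop("underdetermined calibration: fiducials are coplanar")

  # Hartley normalization (mean centroid distance sqrt(2) / sqrt(3))
  norm_sim <- function(p, target) {
    c0 <- colMeans(p)
    sc <- target / mean(sqrt(rowSums(sweep(p, 2, c0)^2)))
    Tm <- diag(ncol(p) + 1)
    diag(Tm)[seq_len(ncol(p))] <- sc
    Tm[seq_len(ncol(p)), ncol(p) + 1] <- -sc * c0
    Tm
  }
  T2 <- norm_sim(x, sqrt(2))
  T3 <- norm_sim(X, sqrt(3))
  Xh <- t(T3 %*% rbind(t(X), 1))
  xh <- t(T2 %*% rbind(t(x), 1))

  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    Xi <- Xh[i, ]
    A[2 * i - 1, ] <- c(Xi, rep(0, 4), -xh[i, 1] * Xi)
    A[2 * i, ] <- c(rep(0, 4), Xi, -xh[i, 2] * Xi)
  }
  p <- svd(A, nu = 0)$v[, 12]
  Pn <- matrix(p, 3, 4, byrow = TRUE)
  P <- solve(T2) %*% Pn %*% T3
  P <- P / sqrt(sum(P[3, 1:3]^2))           # normalize scale

  geom <- projection_geometry(P)
  resid <- project_points(geom, X) - x
  projection_geometry(P, reprojection_rms = sqrt(mean(rowSums(resid^2))))
}

#' Triangulate one 2D point pair into 3D
#'
#' Back-projects the pixel in each calibrated view into a ray and
#' returns the midpoint of the shortest segment joining the two rays
#' (the least-squares ray intersection), plus the mean reprojection
#' residual in px.
#'
#' @param geom_a,geom_b calibrated [projection_geometry] objects.
#' @param pt_a,pt_b length-2 pixel coordinates in views A and B.
#' @return list with `point` (3D mm) and `residual` (mean px).
#' @export
triangulate_point <- function(geom_a, geom_b, pt_a, pt_b) {
  c1 <- camera_center(geom_a); d1 <- backproject_ray(geom_a, pt_a)
  c2 <- camera_center(geom_b); d2 <- backproject_ray(geom_b, pt_b)
  cosang <- abs(sum(d1 * d2))
  if (acos(pmin(1, cosang)) < pi / 180)
    stop("ill-conditioned triangulation: rays are within 1 degree of parallel")
  # minimize |c1 + t1 d1 - c2 - t2 d2|^2
  b <- c2 - c1
  d12 <- sum(d1 * d2)
  t1 <- (sum(b * d1) - d12 * sum(b * d2)) / (1 - d12^2)
  t2 <- (d12 * sum(b * d1) - sum(b * d2)) / (1 - d12^2)
  X <- (c1 + t1 * d1 + c2 + t2 * d2) / 2
  ra <- vnorm(project_points(geom_a, rbind(X)) - pt_a)
  rb <- vnorm(project_points(geom_b, rbind(X)) - pt_b)
  list(point = X, residual = (ra + rb) / 2)
}

#' 2D lumen boundary spline
#'
#' Operator-traced lumen edge in one X-ray view, stored as ordered
#' control points and resampled by normalized arc length.
#'
#' @param points m x 2 matrix of control points (px), m >= 4, ordered
#'   proximal to distal.
#' @param side `"left"` or `"right"` edge of the lumen silhouette.
#' @param view `"A"` or `"B"`.
#' @return object of class `boundary_spline`.
#' @export
boundary_spline <- function(points, side = c("left", "right"), view = c("A", "B")) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("boundary spline needs >= 4 control points")
  side <- match.arg(side); view <- match.arg(view)
  s <- polyline_arclength(points)
  if (max(s) <= 0) stop("degenerate boundary spline")
  structure(list(points = points, param = s / max(s), side = side, view = view),
            class = "boundary_spline")
}

#' Sample a boundary spline at normalized arc-length parameters
#' @param bs a [boundary_spline].
#' @param t parameters in \[0, 1\].
#' @return length(t) x 2 matrix (px).
#' @export
sample_boundary <- function(bs, t) {
  cbind(stats::spline(bs$param, bs$points[, 1], xout = t, method = "natural")$y,
        stats::spline(bs$param, bs$points[, 2], xout = t, method = "natural")$y)
}

# Fundamental matrix mapping view-A pixels to epipolar lines in view B
fundamental_matrix <- function(geom_a, geom_b) {
  Ca <- c(camera_center(geom_a), 1)
  eb <- as.numeric(geom_b$P %*% Ca)
  sv <- svd(geom_a$P)
  Pa_pinv <- sv$v %*% diag(1 / sv$d) %*% t(sv$u)
  skew <- matrix(c(0, eb[3], -eb[2], -eb[3], 0, eb[1], eb[2], -eb[1], 0), 3, 3)
  skew %*% geom_b$P %*% Pa_pinv
}

#' Triangulate the four boundary splines into two 3D boundary curves
#'
#' Correspondence between the two views is established by the
#' epipolar constraint: each sample of a view-A edge is matched with
#' the point where the corresponding view-B edge crosses its epipolar
#' line, walked monotonically along the curve (normalized arc length
#' breaks the tie between multiple crossings and stands in where the
#' edge runs parallel to the epipolar line, e.g. a vessel segment
#' lying in an epipolar plane).  The matched left-edge pair
#' triangulates into the left 3D boundary curve, likewise the right.
#'
#' @param splines list of four [boundary_spline]s covering
#'   left/right x A/B.
#' @param geom_a,geom_b calibrated [projection_geometry] objects.
#' @param n_samples number of parameter values (>= 100).
#' @return list with `left`, `right` (n x 3 matrices, mm), `param`,
#'   and `residual_px` (mean triangulation residual).
#' @export
triangulate_boundaries <- function(splines, geom_a, geom_b, n_samples = 150) {
  n_samples <- max(n_samples, 100L)
  key <- vapply(splines, function(b) paste0(b$side, b$view), character(1))
  need <- c("leftA", "leftB", "rightA", "rightB")
  if (!all(need %in% key)) stop("need the four boundary splines left/right x A/B")
  sp <- setNames(splines[match(need, key)], need)
  t <- seq(0, 1, length.out = n_samples)
  Fm <- fundamental_matrix(geom_a, geom_b)

  match_epipolar <- function(pa, bsb, dense = 8L) {
    ub <- seq(0, 1, length.out = dense * n_samples)
    pb <- sample_boundary(bsb, ub)
    lines <- cbind(pa, 1) %*% t(Fm)               # n x 3 epipolar lines
    D <- lines %*% t(cbind(pb, 1)) /
      sqrt(lines[, 1]^2 + lines[, 2]^2)           # signed px distance
    n <- nrow(pa)
    u_match <- rep(NA_real_, n)
    u_prev <- 0
    for (i in seq_len(n)) {
      di <- D[i, ]
      cross <- which(di[-length(di)] * di[-1] <= 0)
      if (length(cross) == 0) next               # end degeneracy: fill below
      frac <- di[cross] / (di[cross] - di[cross + 1])
      cand <- ub[cross] + frac * (ub[cross + 1] - ub[cross])
      cand_fwd <- cand[cand >= u_prev - 1e-6]
      if (length(cand_fwd) == 0) cand_fwd <- cand
      u_match[i] <- cand_fwd[which.min(abs(cand_fwd - max(t[i], u_prev)))]
      u_prev <- u_match[i]
    }
    ok <- which(!is.na(u_match))
    if (length(ok) < max(4, n %/% 4))
      stop("epipolar matching failed: the views are too degenerate to correspond the boundaries")
    # samples whose epipolar plane leaves the other curve's extent
    # (silhouette ends) get a local linear extrapolation of u(t)
    miss <- which(is.na(u_match))
    if (length(miss) > 0) {
      k <- min(10, length(ok) - 1)
      for (i in miss) {
        near <- ok[order(abs(ok - i))[seq_len(k + 1)]]
        fit <- stats::lm.fit(cbind(1, t[near]), u_match[near])
        u_match[i] <- sum(fit$coefficients * c(1, t[i]))
      }
    }
    pmin(pmax(cummax(u_match), 0), 1)
  }

  tri_curve <- function(bsa, bsb) {
    pa <- sample_boundary(bsa, t)
    pb <- sample_boundary(bsb, match_epipolar(pa, bsb))
    out <- matrix(0, n_samples, 3)
    res <- numeric(n_samples)
    for (i in seq_len(n_samples)) {
      tr <- triangulate_point(geom_a, geom_b, pa[i, ], pb[i, ])
      out[i, ] <- tr$point
      res[i] <- tr$residual
    }
    list(curve = out, res = res)
  }
  L <- tri_curve(sp$leftA, sp$leftB)
  R <- tri_curve(sp$rightA, sp$rightB)

  # ordering sanity: the left-to-right separation vector must not flip
  w <- R$curve - L$curve
  wbar <- colMeans(w)
  if (any(w %*% wbar < 0))
    stop("inconsistent boundary ordering: triangulated boundaries cross")
  # and the two 3D boundaries must project on consistent sides of the
  # vessel in both views (a swapped left/right labeling in one view
  # triangulates to the wrong diagonal)
  side_sign <- function(geom) {
    l2 <- project_points(geom, L$curve)
    r2 <- project_points(geom, R$curve)
    mid <- (l2 + r2) / 2
    tgt <- rbind(mid[-1, , drop = FALSE] - mid[-nrow(mid), , drop = FALSE])
    sep <- (r2 - l2)[-nrow(l2), , drop = FALSE]
    median(tgt[, 1] * sep[, 2] - tgt[, 2] * sep[, 1])
  }
  if (side_sign(geom_a) * side_sign(geom_b) < 0)
    stop("inconsistent boundary ordering between the two views")
  list(left = L$curve, right = R$curve, param = t,
       residual_px = mean(c(L$res, R$res)))
}

#' Derive the 3D arterial centerline from two 3D boundary curves
#'
#' The centerline is the midpoint locus of the two boundary curves at
#' matched parameters, regularized by a smoothing spline per
#' coordinate against arc length, then equipped with arc length and
#' rotation-minimizing frames.
#'
#' @param boundary_a,boundary_b n x 3 matrices sampled at common
#'   parameter values (e.g. from [triangulate_boundaries]).
#' @param smoothing smoothing-spline penalty `lambda` passed to
#'   [stats::smooth.spline]; the default keeps a straight phantom
#'   straight to well under 0.01 mm while suppressing pixel-scale
#'   triangulation noise.
#' @param n_samples number of output centerline samples.
#' @return a [centerline].
#' @export
extract_centerline <- function(boundary_a, boundary_b, smoothing = 1e-6,
                               n_samples = 200) {
  boundary_a <- as.matrix(boundary_a); boundary_b <- as.matrix(boundary_b)
  if (nrow(boundary_a) != nrow(boundary_b))
    stop("boundaries must be sampled at common parameter values")
  mid <- (boundary_a + boundary_b) / 2
  s <- polyline_arclength(mid)
  s_out <- seq(0, max(s), length.out = n_samples)
  sm <- vapply(1:3, function(j) {
    fit <- smooth.spline(s, mid[, j], lambda = smoothing)
    predict(fit, s_out)$y
  }, numeric(n_samples))
  centerline(sm)
}
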