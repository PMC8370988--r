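#' Extract the straightened (OCT) centerline from a label volume
#'
#' The per-slice centroid of all lumen voxels (true and false lumen)
#' assembles into the OCT-based centerline used for rigid alignment
#' with the X-ray centerline.
#'
#' @param volume a [label_volume] in straightened space.
#' @param labels labels treated as lumen.
#' @return a [centerline] (one sample per slice, world mm).
#' @export
centerline_from_label <- function(volume, labels = c(1L, 2L)) {
  d <- dim(volume$array)
  counts <- apply(volume$array, 3, function(sl) sum(sl %in% labels))
  roi <- range(which(counts > 0))
  inside <- seq(roi[1], roi[2])
  if (any(counts[inside] == 0))
    stop(sprintf("empty slice inside ROI at z index %s",
                 paste(inside[counts[inside] == 0], collapse = ", ")))
  ax <- volume$origin[1] + (seq_len(d[1]) - 1) * volume$spacing[1]
  ay <- volume$origin[2] + (seq_len(d[2]) - 1) * volume$spacing[2]
  pts <- t(vapply(inside, function(k) {
    m <- volume$array[, , k] %in% labels
    dim(m) <- d[1:2]
    c(sum(ax * rowSums(m)) / sum(m),
      sum(ay * colSums(m)) / sum(m),
      volume$origin[3] + (k - 1) * volume$spacing[3])
  }, numeric(3)))
  centerline(pts)
}

#' Rigidly align the OCT centerline with the X-ray centerline
#'
#' Builds a piecewise-linear arc-length correspondence through the
#' landmark pairs (endpoint correspondence is assumed when no
#' landmarks are given, i.e. equal ROI extent on both centerlines) and
#' estimates the least-squares rigid transform (Procrustes without
#' scaling) over matched samples.
#'
#' @param oct_cl,xray_cl [centerline] objects.
#' @param landmark_pairs optional n x 2 matrix of matched arc lengths
#'   `(s_oct, s_xray)` in mm, e.g. from arterial side branches.
#' @param n_samples samples used for the rigid fit.
#' @return object of class `centerline_alignment`: list with
#'   `rotation` (3 x 3), `translation` (3), `map` (function
#'   s_oct -> s_xray), `inverse_map`, and `rms_mm` of the fit.
#' @export
align_centerlines <- function(oct_cl, xray_cl, landmark_pairs = NULL,
                              n_samples = 200) {
  L_oct <- centerline_length(oct_cl)
  L_xray <- centerline_length(xray_cl)
  lp <- if (is.null(landmark_pairs)) cbind(c(0, L_oct), c(0, L_xray))
        else as.matrix(landmark_pairs)
  if (nrow(lp) < 2) lp <- rbind(c(0, 0), lp, c(L_oct, L_xray))
  if (lp[1, 1] > 1e-9) lp <- rbind(c(0, 0), lp)
  if (lp[nrow(lp), 1] < L_oct - 1e-9) lp <- rbind(lp, c(L_oct, L_xray))
  if (is.unsorted(lp[, 1], strictly = TRUE) || is.unsorted(lp[, 2], strictly = TRUE))
    stop("landmark arc lengths must be strictly increasing on both centerlines")
  s_map <- function(s) approx(lp[, 1], lp[, 2], xout = s, rule = 2)$y
  s_inv <- function(s) approx(lp[, 2], lp[, 1], xout = s, rule = 2)$y

  s_o <- seq(0, L_oct, length.out = n_samples)
  X <- centerline_at(oct_cl, s_o)$points
  Y <- centerline_at(xray_cl, s_map(s_o))$points
  xb <- colMeans(X); yb <- colMeans(Y)
  H <- t(sweep(X, 2, xb)) %*% sweep(Y, 2, yb)
  sv <- svd(H)
  D <- diag(c(1, 1, det(sv$v %*% t(sv$u))))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- yb - as.numeric(R %*% xb)
  fit <- sweep(X %*% t(R), 2, tr, "+")
  structure(list(rotation = R, translation = tr, map = s_map,
                 inverse_map = s_inv,
                 rms_mm = sqrt(mean(rowSums((fit - Y)^2)))),
            class = "centerline_alignment")
}

#' @export
print.centerline_alignment <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<centerline_alignment> rotation %.2f deg, |t| = %.2f mm, rms %.4f mm\n",
              ang, vnorm(x$translation), x$rms_mm))
  invisible(x)
}

#' Map straightened slices onto the anatomical centerline
#'
#' For every slice of the straightened volume, computes the rigid pose
#' (rotation + translation) that translates the slice to its
#' corresponding arc-length position on the X-ray centerline and
#' rotates it so the slice plane is orthogonal to the centerline
#' tangent.  In-plane orientation follows the rotation-minimizing
#' frame of the X-ray centerline (no twist accumulation); an optional
#' global `roll` rotates all slices about their normals, for
#' landmark-based roll registration.
#'
#' @param oct_cl straightened-space [centerline] (one sample per
#'   slice, from [centerline_from_label]).
#' @param xray_cl anatomical [centerline].
#' @param correspondence a `centerline_alignment` (its arc-length map
#'   is used), or `NULL` for normalized arc-length matching.
#' @param roll global in-plane roll angle in radians (default 0).
#' @return object of class `slice_map`: `z_mm` (source slice world z),
#'   `anchor` (n x 2 in-plane anchor, the per-slice centroid),
#'   `target` (n x 3 target points), `rotation` (3 x 3 x n array).
#' @export
build_slice_map <- function(oct_cl, xray_cl, correspondence = NULL, roll = 0) {
  z_mm <- oct_cl$points[, 3]
  s_src <- z_mm - z_mm[1]
  if (is.null(correspondence)) {
    s_tgt <- s_src / max(s_src) * centerline_length(xray_cl)
  } else {
    s_tgt <- correspondence$map(s_src)
  }
  if (any(s_tgt < -1e-9 | s_tgt > centerline_length(xray_cl) + 1e-9))
    stop("slice correspondence falls outside the X-ray centerline range")
  fr <- centerline_at(xray_cl, s_tgt)
  n <- length(z_mm)
  # anchor the in-plane orientation at the proximal slice: offset the
  # rotation-minimizing frames by the constant roll that makes the
  # first slice pose the minimal rotation carrying the source slice
  # normal (+z) onto the proximal tangent.  Without this, an arbitrary
  # frame seed would add a rigid twist to every slice.
  Rmin <- rotation_between(c(0, 0, 1), fr$tangent[1, ])
  e1_min <- as.numeric(Rmin %*% c(1, 0, 0))
  phi <- atan2(sum(e1_min * fr$binormal[1, ]), sum(e1_min * fr$normal[1, ]))
  cr <- cos(roll + phi); sr <- sin(roll + phi)
  rot <- array(0, c(3, 3, n))
  for (i in seq_len(n)) {
    e1 <- cr * fr$normal[i, ] + sr * fr$binormal[i, ]
    e2 <- -sr * fr$normal[i, ] + cr * fr$binormal[i, ]
    rot[, , i] <- cbind(e1, e2, fr$tangent[i, ])
  }
  structure(list(z_mm = z_mm, anchor = oct_cl$points[, 1:2, drop = FALSE],
                 target = fr$points, rotation = rot, s_target = s_tgt),
            class = "slice_map")
}

#' @export
print.slice_map <- function(x, ...) {
  cat(sprintf("<slice_map> %d slices, target arc length %.2f-%.2f mm\n",
              length(x$z_mm), min(x$s_target), max(x$s_target)))
  invisible(x)
}

#' Dense displacement field on a voxel grid
#'
#' @param vectors 4D array (nx, ny, nz, 3) of per-voxel displacement
#'   vectors in mm.
#' @param spacing,origin grid geometry (mm).
#' @param direction `"forward"` (source to target) or `"inverse"`
#'   (target to source).
#' @return object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing, origin,
                               direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (length(dim(vectors)) != 4 || dim(vectors)[4] != 3)
    stop("vectors must be an (nx, ny, nz, 3) array")
  structure(list(vectors = vectors, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), direction = direction),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$vectors)
  cat(sprintf("<displacement_field> %s, %d x %d x %d, max |u| = %.3f mm\n",
              x$direction, d[1], d[2], d[3],
              sqrt(max(rowSums(matrix(x$vectors, ncol = 3)^2), na.rm = TRUE))))
  invisible(x)
}

#' Forward displacement field of a slice map
#'
#' Evaluates, for every voxel of the straightened grid, the
#' displacement carrying it to its warped position: the slice pose
#' applied to the voxel's in-plane offset from the slice anchor.  The
#' field is defined on the whole grid (the pose extends smoothly off
#' the lumen), which keeps the subsequent dense inversion well posed.
#'
#' @param volume the straightened [label_volume] (defines the grid).
#' @param slice_map a [build_slice_map] result for this grid.
#' @return a forward [displacement_field] on the volume's grid.
#' @export
forward_field <- function(volume, slice_map) {
  d <- dim(volume$array)
  if (length(slice_map$z_mm) != d[3])
    stop("slice map does not cover every slice of the volume")
  ax <- volume$origin[1] + (seq_len(d[1]) - 1) * volume$spacing[1]
  ay <- volume$origin[2] + (seq_len(d[2]) - 1) * volume$spacing[2]
  xg <- matrix(ax, d[1], d[2])
  yg <- matrix(ay, d[1], d[2], byrow = TRUE)
  u <- array(0, c(d[1], d[2], d[3], 3))
  for (k in seq_len(d[3])) {
    R <- slice_map$rotation[, , k]
    q <- slice_map$target[k, ]
    wx <- xg - slice_map$anchor[k, 1]
    wy <- yg - slice_map$anchor[k, 2]
    u[, , k, 1] <- q[1] + R[1, 1] * wx + R[1, 2] * wy - xg
    u[, , k, 2] <- q[2] + R[2, 1] * wx + R[2, 2] * wy - yg
    u[, , k, 3] <- q[3] + R[3, 1] * wx + R[3, 2] * wy -
      (volume$origin[3] + (k - 1) * volume$spacing[3])
  }
  displacement_field(u, volume$spacing, volume$origin, "forward")
}

# Trilinear interpolation of a displacement field at world points
# (n x 3).  Coordinates are clamped to the grid so the field extends
# by its edge values.
interp_field <- function(field, pts) {
  d <- dim(field$vectors)
  g <- sweep(pts, 2, field$origin) / rep(field$spacing, each = nrow(pts))
  g <- pmin(pmax(g, 0), rep(d[1:3] - 1, each = nrow(pts)))
  i0 <- pmin(floor(g), rep(d[1:3] - 2, each = nrow(pts)))
  i0[, 1] <- pmax(i0[, 1], 0); i0[, 2] <- pmax(i0[, 2], 0); i0[, 3] <- pmax(i0[, 3], 0)
  f <- g - i0
  out <- matrix(0, nrow(pts), 3)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  base <- 1 + i0[, 1] + nx * (i0[, 2] + ny * i0[, 3])
  v <- field$vectors
  for (comp in 1:3) {
    off <- (comp - 1) * nx * ny * nz
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) f[, 1] else 1 - f[, 1]) *
           (if (dy) f[, 2] else 1 - f[, 2]) *
           (if (dz) f[, 3] else 1 - f[, 3])
      acc <- acc + w * v[off + base + dx + nx * dy + nx * ny * dz]
    }
    out[, comp] <- acc
  }
  out
}

#' Compute the target grid covering the warped lumen
#'
#' Forward-maps the lumen voxels and returns a grid of the requested
#' spacing covering their bounding box padded by `pad` voxels.
#'
#' @param volume straightened [label_volume].
#' @param forward forward [displacement_field].
#' @param spacing target spacing (default: source spacing).
#' @param pad padding in voxels.
#' @return list with `dim`, `spacing`, `origin` describing the grid.
#' @export
target_grid_for <- function(volume, forward, spacing = NULL, pad = 2) {
  if (is.null(spacing)) spacing <- volume$spacing
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  src <- label_voxel_coords(volume)
  mapped <- src + interp_field(forward, src)
  lo <- apply(mapped, 2, min) - pad * spacing
  hi <- apply(mapped, 2, max) + pad * spacing
  list(dim = as.integer(ceiling((hi - lo) / spacing)) + 1L,
       spacing = spacing, origin = lo)
}

#' Invert a dense forward displacement field
#'
#' Fixed-point iteration `v_{k+1}(y) = -u(y + v_k(y))` on the target
#' grid, starting from `v_0(y) = -u(y)`, until the largest update
#' falls below `tol` voxels or `max_iter` iterations.  The composition
#' residual `max |u(y + v(y)) + v(y)|` is reported on the returned
#' field.
#'
#' @param forward forward [displacement_field].
#' @param target_grid grid description as from [target_grid_for].
#' @param tol convergence tolerance in target voxels (default 0.01).
#' @param max_iter iteration cap (default 50).
#' @param mask optional logical array on the target grid restricting
#'   the inversion (voxels outside keep `NA` vectors).
#' @param init optional initial guess for the inverse vectors (matrix
#'   with one row per `TRUE` mask voxel, or an (nx, ny, nz, 3) array).
#'   For displacements large compared to the source grid extent (e.g.
#'   bending a straightened vessel), a scattered initialization from
#'   the forward-mapped point cloud is required for the fixed point to
#'   start inside its basin of attraction; [warp_to_centerline]
#'   supplies one automatically.
#' @param alpha under-relaxation factor of the fixed-point update
#'   (default 0.5; 1 recovers plain Picard iteration, which is only
#'   contractive for mild bends).  The damped iteration converges
#'   while the slice rotations stay below ~60 degrees; a global roll
#'   near 90 degrees makes the forward Jacobian's eigenvalues purely
#'   imaginary and no damping converges - rotate the source volume
#'   beforehand instead of using such rolls.
#' @param core optional logical array flagging the voxels on which
#'   convergence is required (default: all of `mask`).  Band voxels
#'   outside the warped lumen have no exact preimage - the forward
#'   field only extends there for interpolation - so the composition
#'   residual is meaningful on lumen support.
#' @return an inverse [displacement_field]; attribute
#'   `composition_residual_vox` carries the final residual.
#' @export
invert_field <- function(forward, target_grid, tol = 0.01, max_iter = 50,
                         mask = NULL, init = NULL, alpha = 0.5, core = NULL) {
  d <- target_grid$dim
  sp <- target_grid$spacing
  if (is.null(mask)) mask <- array(TRUE, d)
  idx <- which(mask)
  ijk <- arrayInd(idx, d)
  y <- sweep(sweep(ijk - 1, 2, sp, "*"), 2, target_grid$origin, "+")
  if (is.null(init)) {
    v <- -interp_field(forward, y)
  } else if (is.array(init) && length(dim(init)) == 4) {
    n_vox <- prod(d)
    v <- cbind(init[idx], init[idx + n_vox], init[idx + 2 * n_vox])
  } else {
    v <- as.matrix(init)
    if (nrow(v) != length(idx)) stop("init must have one row per mask voxel")
  }
  vox <- min(sp)
  in_core <- if (is.null(core)) rep(TRUE, length(idx)) else core[idx]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # damped fixed point: plain Picard is not contractive once the
    # slice rotations get large (|grad u| -> 1), under-relaxation is
    r <- v + interp_field(forward, y + v)
    delta <- max(abs(r[in_core, ])) / vox
    if (delta < tol) { converged <- TRUE; break }
    v <- v - alpha * r
  }
  resid <- max(sqrt(rowSums((interp_field(forward, y + v) + v)[in_core, , drop = FALSE]^2))) / vox
  if (!converged)
    stop(sprintf("displacement inversion did not converge in %d iterations (last update %.3g voxels, composition residual %.3g voxels)",
                 max_iter, delta, resid))
  vec <- array(NA_real_, c(d, 3))
  n_vox <- prod(d)
  for (comp in 1:3) vec[idx + (comp - 1) * n_vox] <- v[, comp]
  out <- displacement_field(vec, sp, target_grid$origin, "inverse")
  attr(out, "composition_residual_vox") <- resid
  attr(out, "iterations") <- it
  out
}

#' Warp a label volume through an inverse displacement field
#'
#' Each target voxel takes the label of the source voxel nearest to
#' `y + v(y)` (nearest-neighbor pullback; labels are categorical).
#' Target voxels with undefined inverse vectors stay background.  An
#' error is raised if warped lumen labels touch the target boundary,
#' i.e. the target grid clips the mapped lumen.
#'
#' @param volume straightened source [label_volume].
#' @param inverse inverse [displacement_field] on the target grid.
#' @param target_grid grid description matching `inverse`.
#' @return warped [label_volume] in anatomical space.
#' @export
warp_labels <- function(volume, inverse, target_grid) {
  d <- target_grid$dim
  sp <- target_grid$spacing
  defined <- which(!is.na(inverse$vectors[, , , 1]))
  ijk <- arrayInd(defined, d)
  y <- sweep(sweep(ijk - 1, 2, sp, "*"), 2, target_grid$origin, "+")
  n_vox <- prod(d)
  v <- cbind(inverse$vectors[defined],
             inverse$vectors[defined + n_vox],
             inverse$vectors[defined + 2 * n_vox])
  src <- y + v
  sd <- dim(volume$array)
  si <- round(sweep(src, 2, volume$origin) / rep(volume$spacing, each = nrow(src))) + 1
  inside <- si[, 1] >= 1 & si[, 1] <= sd[1] &
            si[, 2] >= 1 & si[, 2] <= sd[2] &
            si[, 3] >= 1 & si[, 3] <= sd[3]
  lab <- integer(nrow(si))
  lab[inside] <- volume$array[cbind(si[inside, 1], si[inside, 2], si[inside, 3])]
  arr <- array(0L, d)
  arr[defined] <- lab
  on_boundary <- ijk[, 1] %in% c(1L, d[1]) | ijk[, 2] %in% c(1L, d[2]) |
                 ijk[, 3] %in% c(1L, d[3])
  if (any(lab > 0L & on_boundary))
    stop("target grid clips the mapped lumen; enlarge the grid padding")
  label_volume(arr, spacing = sp, origin = target_grid$origin)
}

# Occupancy mask of the warped lumen on the target grid (dilated by
# `dilate` voxels) plus a scattered initial guess of the inverse
# displacement: per occupied voxel the mean of (source - mapped) over
# the forward-mapped source points landing in it, propagated to the
# dilated band by neighborhood averaging.
warped_lumen_scatter <- function(volume, forward, target_grid, dilate = 2L) {
  src <- label_voxel_coords(volume)
  mapped <- src + interp_field(forward, src)
  d <- target_grid$dim
  ijk <- round(sweep(mapped, 2, target_grid$origin) /
                 rep(target_grid$spacing, each = nrow(mapped))) + 1
  keep <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
          ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
          ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  ijk <- ijk[keep, , drop = FALSE]
  vsc <- (src - mapped)[keep, , drop = FALSE]
  lin <- ijk[, 1] + d[1] * (ijk[, 2] - 1) + d[1] * d[2] * (ijk[, 3] - 1)
  agg <- rowsum(cbind(vsc, 1), lin)
  occ <- array(FALSE, d)
  occ_lin <- as.numeric(rownames(agg))
  occ[occ_lin] <- TRUE
  n_vox <- prod(d)
  vinit <- array(NA_real_, c(d, 3))
  for (comp in 1:3) vinit[occ_lin + (comp - 1) * n_vox] <- agg[, comp] / agg[, 4]

  mask <- occ
  if (dilate > 0) {
    shift_arr <- function(a, dx, dy, dz) {
      xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
      zs <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
      a[xs, ys, zs]
    }
    for (pass in seq_len(dilate)) {
      grown <- mask
      for (sh in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
        grown <- grown | shift_arr(mask, sh[1], sh[2], sh[3])
      mask <- grown
    }
    # propagate the initial guess into the dilated band
    repeat {
      hole <- mask & is.na(vinit[, , , 1])
      if (!any(hole)) break
      acc <- array(0, c(d, 3)); cnt <- array(0, d)
      for (sh in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
        nb <- shift_arr(vinit[, , , 1], sh[1], sh[2], sh[3])
        def <- !is.na(nb)
        cnt <- cnt + def
        for (comp in 1:3) {
          nbv <- shift_arr(vinit[, , , comp], sh[1], sh[2], sh[3])
          nbv[!def] <- 0
          acc[, , , comp] <- acc[, , , comp] + nbv
        }
      }
      fill <- hole & cnt > 0
      if (!any(fill)) break
      fidx <- which(fill)
      for (comp in 1:3)
        vinit[fidx + (comp - 1) * n_vox] <- acc[fidx + (comp - 1) * n_vox] / cnt[fidx]
    }
  }
  list(mask = mask, init = vinit, core = occ)
}

#' Warp a straightened label volume onto an anatomical centerline
#'
#' Convenience wrapper chaining [build_slice_map], [forward_field],
#' [target_grid_for], [invert_field] (restricted to a dilated band
#' around the warped lumen) and [warp_labels].
#'
#' @param volume straightened [label_volume].
#' @param xray_cl anatomical [centerline].
#' @param correspondence optional `centerline_alignment`.
#' @param spacing target spacing (default: source spacing).
#' @param roll global roll (radians).
#' @param tol,max_iter passed to [invert_field].
#' @return list with `warped` ([label_volume]), `forward`, `inverse`
#'   (displacement fields), `slice_map`, `target_grid`, and
#'   `composition_residual_vox`.
#' @export
warp_to_centerline <- function(volume, xray_cl, correspondence = NULL,
                               spacing = NULL, roll = 0,
                               tol = 0.01, max_iter = 50) {
  oct_cl <- centerline_from_label(volume)
  # reject bends tighter than 5 x lumen radius: the slab self-intersects
  r_lumen <- sqrt(max(slice_areas(volume)) / pi)
  curv <- path_max_curvature(xray_cl)
  if (curv > 0 && 1 / curv < 5 * r_lumen)
    stop(sprintf("centerline bend radius %.1f mm is below 5 x lumen radius (%.1f mm); slices would self-intersect",
                 1 / curv, 5 * r_lumen))
  sm <- build_slice_map(oct_cl, xray_cl, correspondence, roll = roll)
  fwd <- forward_field(volume, sm)
  tg <- target_grid_for(volume, fwd, spacing = spacing)
  sc <- warped_lumen_scatter(volume, fwd, tg, dilate = 2L)
  inv <- invert_field(fwd, tg, tol = tol, max_iter = max_iter,
                      mask = sc$mask, init = sc$init, core = sc$core)
  warped <- warp_labels(volume, inv, tg)
  list(warped = warped, forward = fwd, inverse = inv, slice_map = sm,
       target_grid = tg,
       composition_residual_vox = attr(inv, "composition_residual_vox"))
}

# Maximum discrete curvature (1/mm) of a centerline polyline
path_max_curvature <- function(cl) {
  p <- cl$points
  n <- nrow(p)
  if (n < 3) return(0)
  i <- 2:(n - 1)
  a <- p[i, ] - p[i - 1, ]
  b <- p[i + 1, ] - p[i, ]
  la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2))
  cosang <- pmin(1, pmax(-1, rowSums(a * b) / (la * lb)))
  max(2 * sin(acos(cosang) / 2) / pmax(sqrt(la * lb), 1e-12), 0)
}
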