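#' Per-frame OCT lumen contour set
#'
#' One OCT pullback frame: its index (0 = distal end of the pullback),
#' the traced lumen contours (true lumen and, for dissected frames,
#' separate false-lumen contours) in frame-plane mm, and a quality
#' flag.  Frames where more than one quadrant of the lumen border is
#' not visible are excluded by the operator; excluded frames carry no
#' contours and are filled later by slice interpolation.
#'
#' @param frame_index 0-based integer frame index.
#' @param contours list of `list(region_tag, points)` where
#'   `region_tag` is `"true_lumen"` or `"false_lumen"` and `points` an
#'   m x 2 matrix (mm) of ordered polygon vertices (closed implicitly).
#' @param quality `"ok"` or `"excluded"`.
#' @param z_mm arc-length position of the frame along the pullback.
#' @param pixel_size native in-plane pixel size (mm).
#' @return object of class `contour_set`.
#' @export
contour_set <- function(frame_index, contours = list(),
                        quality = c("ok", "excluded"),
                        z_mm = NA_real_, pixel_size = 0.0102) {
  quality <- match.arg(quality)
  if (quality == "excluded" && length(contours) > 0)
    stop("excluded frames must carry no contours")
  for (ct in contours) {
    if (!ct$region_tag %in% c("true_lumen", "false_lumen"))
      stop("contour region_tag must be true_lumen or false_lumen")
    if (nrow(ct$points) < 3)
      stop(sprintf("frame %d: contour has fewer than 3 points", frame_index))
  }
  structure(list(frame_index = as.integer(frame_index), contours = contours,
                 quality = quality, z_mm = z_mm, pixel_size = pixel_size),
            class = "contour_set")
}

# Even-odd scanline fill of a closed polygon at grid voxel centers.
# poly: m x 2 (mm); ax, ay: voxel-center coordinates per axis.
# Returns a logical nx x ny matrix.
polygon_fill <- function(poly, ax, ay) {
  m <- nrow(poly)
  # detect an unclosed trace: the implicit closing edge should not be a
  # large fraction of the perimeter
  per <- polyline_arclength(rbind(poly, poly[1, ]))
  closing <- vnorm(poly[1, ] - poly[m, ])
  if (closing > 0.35 * max(per)) stop("open contour")
  if (vnorm(poly[1, ] - poly[m, ]) < 1e-12) poly <- poly[-m, , drop = FALSE]
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  out <- matrix(FALSE, length(ax), length(ay))
  jr <- which(ay >= min(y1) - 1e-12 & ay <= max(y1) + 1e-12)
  for (j in jr) {
    y <- ay[j]
    crossing <- (y1 <= y) != (y2 <= y)
    if (!any(crossing)) next
    cx <- x1[crossing] + (y - y1[crossing]) *
      (x2[crossing] - x1[crossing]) / (y2[crossing] - y1[crossing])
    out[, j] <- (findInterval(ax, sort(cx)) %% 2L) == 1L
  }
  out
}

#' Rasterize OCT contour frames into a straightened label volume
#'
#' Each annotated frame is rasterized by even-odd point-in-polygon
#' fill at voxel centers: true-lumen contours first (label 1), then
#' false-lumen contours (label 2, which wins on overlap because
#' dissection membranes are thin and false-lumen attribution drives
#' the downstream area statistics).  Excluded frames are left empty
#' for [interpolate_missing].
#'
#' @param frames list of [contour_set]s sorted by `frame_index`.
#' @param pixel_size in-plane voxel size in mm (default 0.0102, the
#'   native OCT label resolution).
#' @param frame_spacing slice spacing in mm (default 0.2).
#' @param grid_extent in-plane grid size in px; defaults to the
#'   smallest even grid covering all contours plus a 2-voxel margin.
#' @return a [label_volume] centered on the catheter axis, slice `k`
#'   (1-based) at frame index `k - 1`.
#' @export
contours_to_labels <- function(frames, pixel_size = 0.0102, frame_spacing = 0.2,
                               grid_extent = NULL) {
  if (pixel_size <= 0 || frame_spacing <= 0)
    stop("pixel_size and frame_spacing must be > 0")
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (is.unsorted(idx, strictly = TRUE)) stop("frames must be sorted by index")
  if (is.null(grid_extent)) {
    rmax <- 0
    for (f in frames) for (ct in f$contours)
      rmax <- max(rmax, max(abs(ct$points)))
    grid_extent <- 2 * ceiling(rmax / pixel_size + 2)
  }
  n <- grid_extent
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_size
  nz <- max(idx) + 1L
  arr <- array(0L, c(n, n, nz))
  for (f in frames) {
    if (f$quality == "excluded" || length(f$contours) == 0) next
    sl <- matrix(0L, n, n)
    ord <- order(vapply(f$contours, function(ct) ct$region_tag == "false_lumen", logical(1)))
    for (ct in f$contours[ord]) {
      mask <- tryCatch(polygon_fill(ct$points, ax, ax),
                       error = function(e)
                         stop(sprintf("frame %d: %s", f$frame_index, conditionMessage(e))))
      sl[mask] <- if (ct$region_tag == "false_lumen") 2L else 1L
    }
    arr[, , f$frame_index + 1L] <- sl
  }
  label_volume(arr, spacing = c(pixel_size, pixel_size, frame_spacing),
               origin = c(ax[1], ax[1], 0))
}

# Signed distance (in pixels, positive inside) of a binary slice.
# Degenerate all-background / all-foreground slices get a saturated
# constant so that interpolation against them tapers rather than jumps.
slice_sdf <- function(mask) {
  cap <- sum(dim(mask))
  if (!any(mask)) return(matrix(-cap, nrow(mask), ncol(mask)))
  if (all(mask)) return(matrix(cap, nrow(mask), ncol(mask)))
  storage.mode(mask) <- "double"
  EBImage::distmap(mask) - EBImage::distmap(1 - mask)
}

#' Fill unannotated slices by signed-distance interpolation
#'
#' Each missing slice strictly between two annotated slices is filled,
#' per label, by linear interpolation of the slices' signed distance
#' functions thresholded at zero, which morphs shapes smoothly instead
#' of copying the nearer neighbor.  Missing slices beyond the first or
#' last annotated slice are nearest-neighbor copies.  A plain
#' slice-copy mode is available as a fallback.
#'
#' @param volume a [label_volume] with empty slices where no
#'   annotation exists.
#' @param annotated integer vector of 1-based annotated slice indices.
#' @param max_gap largest allowed run of consecutive missing slices
#'   (default 10).
#' @param method `"sdf"` (default) or `"copy"`.
#' @return a [label_volume] with every slice populated.
#' @export
interpolate_missing <- function(volume, annotated, max_gap = 10,
                                method = c("sdf", "copy")) {
  method <- match.arg(method)
  annotated <- sort(unique(as.integer(annotated)))
  nz <- dim(volume$array)[3]
  if (length(annotated) < 2) stop("need >= 2 annotated slices")
  if (any(annotated < 1 | annotated > nz)) stop("annotated indices out of range")
  gaps <- diff(annotated) - 1L
  if (any(gaps > max_gap))
    stop(sprintf("gap of %d missing slices (between annotated slices %s) exceeds max_gap = %d",
                 max(gaps), paste(annotated[which.max(gaps) + 0:1], collapse = "-"), max_gap))
  arr <- volume$array
  sdf_cache <- new.env(parent = emptyenv())
  get_sdf <- function(z, lab) {
    key <- paste0(z, "_", lab)
    if (is.null(sdf_cache[[key]]))
      sdf_cache[[key]] <- slice_sdf(arr[, , z] == lab)
    sdf_cache[[key]]
  }
  for (z in seq_len(nz)) {
    if (z %in% annotated) next
    lo <- max(annotated[annotated < z], -Inf)
    hi <- min(annotated[annotated > z], Inf)
    if (!is.finite(lo)) { arr[, , z] <- arr[, , hi]; next }
    if (!is.finite(hi)) { arr[, , z] <- arr[, , lo]; next }
    if (method == "copy") {
      src <- if ((z - lo) <= (hi - z)) lo else hi
      arr[, , z] <- arr[, , src]
      next
    }
    w <- (hi - z) / (hi - lo)
    sl <- matrix(0L, dim(arr)[1], dim(arr)[2])
    for (lab in c(1L, 2L)) {
      sdf <- w * get_sdf(lo, lab) + (1 - w) * get_sdf(hi, lab)
      sl[sdf > 0] <- lab
    }
    arr[, , z] <- sl
  }
  label_volume(arr, spacing = volume$spacing, origin = volume$origin)
}

#' Resample a label volume to a new spacing (nearest neighbor)
#'
#' Labels are categorical, so resampling uses nearest-neighbor lookup
#' on the new grid covering the same physical extent.  The canonical
#' use is the down-sampling of the native OCT label volume
#' (0.0102 x 0.0102 x 0.2 mm) to the isotropic 0.075 mm working
#' resolution of the warping stage.
#'
#' @param volume a [label_volume].
#' @param target_spacing scalar or length-3 spacing in mm.
#' @return a [label_volume] on the new grid.
#' @export
resample_volume <- function(volume, target_spacing = 0.075) {
  sp <- as.numeric(target_spacing)
  if (length(sp) == 1) sp <- rep(sp, 3)
  if (any(sp <= 0)) stop("target_spacing must be > 0")
  d <- dim(volume$array)
  extent <- d * volume$spacing
  nd <- pmax(1L, round(extent / sp))
  if (any(nd == 1L)) warning("resampled volume is degenerate (1 voxel) along an axis")
  # new voxel centers, aligned so both grids cover the same extent
  idx <- lapply(1:3, function(a) {
    x <- volume$origin[a] - volume$spacing[a] / 2 + (seq_len(nd[a]) - 0.5) * sp[a]
    pmin(pmax(round((x - volume$origin[a]) / volume$spacing[a]) + 1, 1L), d[a])
  })
  label_volume(volume$array[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
               spacing = sp,
               origin = volume$origin - volume$spacing / 2 + sp / 2)
}

#' Write contour frames to CSV
#'
#' Long format with one row per polygon vertex:
#' `frame_index, region_tag, x_mm, y_mm`; excluded frames appear as a
#' single row with `region_tag = "excluded"` and `NA` coordinates.
#'
#' @param frames list of [contour_set]s.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(frames, path) {
  rows <- lapply(frames, function(f) {
    if (f$quality == "excluded" || length(f$contours) == 0)
      return(data.frame(frame_index = f$frame_index, contour = 0L,
                        region_tag = if (f$quality == "excluded") "excluded" else "empty",
                        x_mm = NA_real_, y_mm = NA_real_))
    do.call(rbind, lapply(seq_along(f$contours), function(i) {
      ct <- f$contours[[i]]
      data.frame(frame_index = f$frame_index, contour = i,
                 region_tag = ct$region_tag,
                 x_mm = ct$points[, 1], y_mm = ct$points[, 2])
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read contour frames from the CSV layout of [write_contours_csv]
#' @param path CSV file.
#' @param pixel_size,frame_spacing acquisition metadata to attach.
#' @return list of [contour_set]s.
#' @export
read_contours_csv <- function(path, pixel_size = 0.0102, frame_spacing = 0.2) {
  df <- read.csv(path)
  lapply(sort(unique(df$frame_index)), function(k) {
    sub <- df[df$frame_index == k, ]
    if (any(sub$region_tag == "excluded"))
      return(contour_set(k, list(), quality = "excluded",
                         z_mm = k * frame_spacing, pixel_size = pixel_size))
    if (any(sub$region_tag == "empty"))
      return(contour_set(k, list(), quality = "ok",
                         z_mm = k * frame_spacing, pixel_size = pixel_size))
    contours <- lapply(split(sub, sub$contour), function(g)
      list(region_tag = g$region_tag[1], points = cbind(g$x_mm, g$y_mm)))
    contour_set(k, unname(contours), quality = "ok",
                z_mm = k * frame_spacing, pixel_size = pixel_size)
  })
}
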