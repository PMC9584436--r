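#' Maximum intensity projection
#'
#' Collapses a volume along Z: each output pixel is the maximum of that pixel
#' across all frames.
#'
#' @param volume numeric array `H x W x Z` (or a matrix, treated as Z = 1).
#' @return An `H x W` matrix with attribute `"volume_index"` when present on
#'   the input.
#' @export
max_intensity_projection <- function(volume) {
  if (is.matrix(volume)) return(volume)
  stopif_not(length(dim(volume)) == 3 && dim(volume)[3] >= 1,
             "volume must be an H x W x Z array with Z >= 1")
  frames <- lapply(seq_len(dim(volume)[3]), function(k) volume[, , k])
  mip <- Reduce(pmax, frames)
  attr(mip, "volume_index") <- attr(volume, "volume_index")
  mip
}

#' Segment the head region from a projection image
#'
#' Median blur, morphological closing (the dilation disc slightly larger than
#' the erosion disc, to fuse neighbouring nuclei into one connected head
#' region without merging head and body), global Otsu threshold, connected
#' components. The largest-area component is the head; all others are body
#' regions.
#'
#' @param mip `H x W` matrix (e.g. from [max_intensity_projection()]).
#' @param median_size half-size of the median filter (2 gives a 5 x 5 filter).
#' @param dilate_radius,erode_radius disc radii (px) of the closing operation;
#'   `dilate_radius` should exceed `erode_radius`.
#' @param threshold `"otsu"` (global) or a numeric threshold on the `[0, 1]`
#'   rescaled image.
#' @return An object of class `worm_head`: `head_contour` (ordered 0-based
#'   `(x, y)` matrix), `body_contours` (list), `head_mask` (`H x W` logical),
#'   `head_bbox` (`c(x, y, w, h)`), `head_area`, `body_areas`.
#' @export
segment_head <- function(mip, median_size = 2, dilate_radius = 5,
                         erode_radius = 4, threshold = "otsu") {
  rng <- range(mip)
  stopif_not(rng[2] > rng[1], "cannot segment a constant image")
  img01 <- (mip - rng[1]) / (rng[2] - rng[1])
  e <- EBImage::Image(t(img01))
  e <- EBImage::medianFilter(e, median_size)
  thr <- if (identical(threshold, "otsu")) EBImage::otsu(e) else threshold
  mask <- e > thr
  # closing on the binary foreground: the dilation disc is strictly larger
  # than the erosion disc, so separated nuclei fuse into one connected head
  # with a small safety margin
  mask <- EBImage::dilate(mask, EBImage::makeBrush(2L * dilate_radius + 1L,
                                                   "disc"))
  mask <- EBImage::erode(mask, EBImage::makeBrush(2L * erode_radius + 1L,
                                                  "disc"))
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  nobj <- max(lab)
  if (nobj < 1) abort("no foreground component found")
  areas <- tabulate(as.integer(lab)[as.integer(lab) > 0], nbins = nobj)
  head_id <- which.max(areas)
  contours <- EBImage::ocontour(lab)
  head_contour <- contours[[head_id]]
  colnames(head_contour) <- c("x", "y")
  body_ids <- setdiff(seq_len(nobj), head_id)
  head_mask <- t(EBImage::imageData(lab) == head_id)  # back to plain H x W
  head_mask <- matrix(as.logical(head_mask), nrow(head_mask))
  xs <- range(head_contour[, 1]); ys <- range(head_contour[, 2])
  structure(list(
    head_contour = head_contour,
    body_contours = lapply(contours[body_ids], function(ct) {
      colnames(ct) <- c("x", "y"); ct
    }),
    head_mask = head_mask,
    head_bbox = c(x = xs[1], y = ys[1], w = diff(xs) + 1, h = diff(ys) + 1),
    head_area = areas[head_id],
    body_areas = areas[body_ids]), class = "worm_head")
}

# Signed extent of the mask along direction u through O: march along the ray
# in sub-pixel steps and return the parameter range (t_neg, t_pos) of the
# contiguous in-mask run containing O.
mask_chord <- function(O, u, mask, step = 0.5) {
  H <- nrow(mask); W <- ncol(mask)
  tmax <- sqrt(H^2 + W^2)
  ts <- seq(0, tmax, by = step)
  run_end <- function(sgn) {
    xs <- O[1] + sgn * ts * u[1]; ys <- O[2] + sgn * ts * u[2]
    ok <- xs >= 0 & xs <= W - 1 & ys >= 0 & ys <= H - 1
    inm <- ok
    inm[ok] <- mask[cbind(round(ys[ok]) + 1, round(xs[ok]) + 1)]
    out <- which(!inm)
    if (length(out) == 0) sgn * tmax else sgn * ts[max(1L, out[1] - 1L)]
  }
  c(neg = run_end(-1), pos = run_end(1))
}

#' Build the worm-intrinsic coordinate system
#'
#' From the head's contour and projection intensities: points of interest are
#' head pixels at least one standard deviation above the head mean; the
#' origin `O` is their intensity-weighted centre of mass; the
#' anterior-posterior axis is the longest chord through `O` (direction search
#' at 1 degree resolution against the polygonal contour, ties broken by the
#' smaller angle index); the ventral-dorsal axis is the perpendicular chord.
#' The side of each axis holding more points of interest defines anterior and
#' ventral, exploiting the anterior-dense, crawling-on-its-side anatomy of the
#' head ganglion. Exactly tied counts are broken toward the side containing
#' the contour point farthest from `O`, with a warning.
#'
#' @param head a `worm_head` from [segment_head()].
#' @param mip the projection image used for intensities.
#' @param angle_step chord-search resolution in degrees.
#' @return An object of class `worm_frame`: origin `O`, endpoints `P_a`,
#'   `P_p`, `P_v`, `P_d` (0-based pixel coords), unit axis vectors `ap`
#'   (anterior positive) and `vd` (ventral positive), and moment diagnostics
#'   `M00`, `M10`, `M01`.
#' @export
build_worm_frame <- function(head, mip, angle_step = 1) {
  m <- head$head_mask
  stopif_not(any(m), "head mask is empty")
  vals <- mip[m]
  # capped at the in-mask maximum so that a (near-)uniform head still yields
  # points of interest
  thr <- min(mean(vals) + sd(vals), max(vals))
  idx <- which(m & mip >= thr, arr.ind = TRUE)
  if (nrow(idx) < 3) abort("too few points of interest in the head")
  px <- idx[, 2] - 1; py <- idx[, 1] - 1   # 0-based (x, y)
  wgt <- mip[idx]
  M00 <- sum(wgt); M10 <- sum(px * wgt); M01 <- sum(py * wgt)
  O <- c(M10 / M00, M01 / M00)

  poly <- head$head_contour
  if (!head$head_mask[round(O[2]) + 1, round(O[1]) + 1])
    abort("degenerate head: centre of mass outside the head mask")
  angles <- seq(0, 180 - angle_step, by = angle_step) * pi / 180
  best <- list(len = -1)
  for (i in seq_along(angles)) {
    u <- c(cos(angles[i]), sin(angles[i]))
    ch <- mask_chord(O, u, head$head_mask)
    len <- ch["pos"] - ch["neg"]
    if (len > best$len + 1e-9) best <- list(len = len, u = u, ch = ch)
  }
  if (best$len <= 0) abort("degenerate head contour: chord search failed")
  u <- best$u
  Pa <- unname(O + best$ch[["pos"]] * u)
  Pp <- unname(O + best$ch[["neg"]] * u)
  v <- c(-u[2], u[1])
  chv <- mask_chord(O, v, head$head_mask)
  if (chv["pos"] - chv["neg"] <= 0)
    abort("degenerate head contour: perpendicular chord failed")
  Pv <- unname(O + chv[["pos"]] * v)
  Pd <- unname(O + chv[["neg"]] * v)

  side_counts <- function(dir) {
    s <- (px - O[1]) * dir[1] + (py - O[2]) * dir[2]
    c(sum(s > 0), sum(s < 0))
  }
  orient <- function(dir, Pplus, Pminus, axis_name) {
    cnt <- side_counts(dir)
    if (cnt[1] == cnt[2]) {
      warn(sprintf("tied point-of-interest counts on the %s axis; %s",
                   axis_name, "breaking toward the farthest contour point"))
      d <- sqrt((poly[, 1] - O[1])^2 + (poly[, 2] - O[2])^2)
      far <- poly[which.max(d), ]
      s <- (far[1] - O[1]) * dir[1] + (far[2] - O[2]) * dir[2]
      cnt <- if (s >= 0) c(1, 0) else c(0, 1)
    }
    if (cnt[1] >= cnt[2]) list(dir = dir, Pplus = Pplus, Pminus = Pminus)
    else list(dir = -dir, Pplus = Pminus, Pminus = Pplus)
  }
  o_ap <- orient(u, Pa, Pp, "ventral-dorsal")   # split by the V-D axis
  o_vd <- orient(c(-o_ap$dir[2], o_ap$dir[1]), Pv, Pd, "anterior-posterior")

  structure(list(O = O, P_a = o_ap$Pplus, P_p = o_ap$Pminus,
                 P_v = o_vd$Pplus, P_d = o_vd$Pminus,
                 ap = o_ap$dir, vd = o_vd$dir,
                 M00 = M00, M10 = M10, M01 = M01), class = "worm_frame")
}

#' Transform 3D points into worm coordinates
#'
#' Projects pixel-space points onto the worm frame: `x_ap` along the
#' anterior-posterior axis (anterior positive), `y_vd` along the
#' ventral-dorsal axis (ventral positive), `z` the axial offset in frames
#' times `z_scale`. Cylindrical coordinates use `rho = sqrt(x_ap^2 + y_vd^2)`
#' and an azimuth measured from the ventral axis,
#' `phi = atan2(x_ap, y_vd)` remapped to `[-pi/2, 3*pi/2)`, so the ventral
#' half is exactly `phi` in `[-pi/2, pi/2]` and the dorsal half is
#' `(pi/2, 3*pi/2)`.
#'
#' @param points data frame with columns `x`, `y` (0-based px) and optionally
#'   `z` (frame units).
#' @param frame a `worm_frame`.
#' @param z_scale axial scale (e.g. microns per frame; default 1 keeps frame
#'   units).
#' @param origin length-3 origin `c(x, y, z)` in pixel/frame units; defaults
#'   to the frame origin `O` at `z = 0`. For neuron features this is the
#'   queried neuron's centroid.
#' @return A tibble `x_ap, y_vd, z, rho, phi`.
#' @export
to_worm_coords <- function(points, frame, z_scale = 1, origin = NULL) {
  origin <- origin %||% c(frame$O, 0)
  dx <- points$x - origin[1]
  dy <- points$y - origin[2]
  zz <- if (!is.null(points[["z"]])) (points[["z"]] - origin[3]) * z_scale else
    rep(0, length(dx))
  x_ap <- dx * frame$ap[1] + dy * frame$ap[2]
  y_vd <- dx * frame$vd[1] + dy * frame$vd[2]
  phi <- atan2(x_ap, y_vd)
  phi <- ifelse(phi < -pi / 2, phi + 2 * pi, phi)
  tibble(x_ap = x_ap, y_vd = y_vd, z = zz,
         rho = sqrt(x_ap^2 + y_vd^2), phi = phi)
}

#' Inverse of [to_worm_coords()]
#'
#' @param wc tibble with `x_ap`, `y_vd`, `z` columns.
#' @inheritParams to_worm_coords
#' @return A tibble `x, y, z` in pixel/frame units.
#' @export
from_worm_coords <- function(wc, frame, z_scale = 1, origin = NULL) {
  origin <- origin %||% c(frame$O, 0)
  tibble(x = origin[1] + wc$x_ap * frame$ap[1] + wc$y_vd * frame$vd[1],
         y = origin[2] + wc$x_ap * frame$ap[2] + wc$y_vd * frame$vd[2],
         z = origin[3] + wc$z / z_scale)
}

#' Run pre-processing on one volume
#'
#' Convenience wrapper: projection, head segmentation, worm frame.
#'
#' @param volume `H x W x Z` array.
#' @param ... passed to [segment_head()].
#' @return A list `mip`, `head`, `frame`.
#' @export
preprocess_volume <- function(volume, ...) {
  mip <- max_intensity_projection(volume)
  head <- segment_head(mip, ...)
  frame <- build_worm_frame(head, mip)
  list(mip = mip, head = head, frame = frame)
}
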