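#' Find local intensity maxima
#'
#' A pixel is a peak if it equals the maximum of its square neighbourhood and
#' strictly exceeds the intensity floor. With a mask, only peaks inside the
#' mask are kept and the default floor is the in-mask mean plus one standard
#' deviation. Peaks are returned in deterministic row-major order.
#'
#' @param img `H x W` matrix.
#' @param mask optional `H x W` logical matrix restricting the search.
#' @param neighborhood odd window size (default 5).
#' @param floor intensity floor; default `mean + floor_k * sd` over the mask
#'   (or whole image).
#' @param floor_k multiplier on the standard deviation in the default floor.
#' @return A tibble `px, py, value` with 0-based pixel coordinates.
#' @export
find_local_maxima <- function(img, mask = NULL, neighborhood = 5,
                              floor = NULL, floor_k = 2) {
  stopif_not(neighborhood %% 2 == 1, "neighborhood must be odd")
  r <- (neighborhood - 1L) / 2L
  H <- nrow(img); W <- ncol(img)
  ref <- if (!is.null(mask)) img[mask] else img
  floor <- floor %||% (mean(ref) + floor_k * sd(ref))
  # separable running max with -Inf padding
  shift2 <- function(m, dy, dx) {
    out <- matrix(-Inf, H, W)
    ys <- max(1, 1 + dy):min(H, H + dy)
    xs <- max(1, 1 + dx):min(W, W + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  rowmax <- img
  for (d in seq_len(r)) rowmax <- pmax(rowmax, shift2(img, 0, d), shift2(img, 0, -d))
  winmax <- rowmax
  for (d in seq_len(r)) winmax <- pmax(winmax, shift2(rowmax, d, 0), shift2(rowmax, -d, 0))
  is_peak <- img == winmax & img > floor
  if (!is.null(mask)) is_peak <- is_peak & mask
  idx <- which(t(is_peak))           # row-major: scan y, then x within y
  if (length(idx) == 0) return(tibble(px = integer(), py = integer(),
                                      value = numeric()))
  px <- (idx - 1L) %% W
  py <- (idx - 1L) %/% W
  tibble(px = as.integer(px), py = as.integer(py),
         value = img[cbind(py + 1L, px + 1L)])
}

#' Build anchor boxes centred on peaks
#'
#' One box per (peak, size) pair, centred on the peak. Boxes reaching outside
#' the image are retained and flagged `clipped`.
#'
#' @param peaks tibble from [find_local_maxima()].
#' @param sizes integer vector of (odd) anchor box side lengths.
#' @param img_size `c(W, H)` for the clipped flag.
#' @param z frame index stored in the anchors.
#' @return A tibble `x, y, w, h, z, px, py, clipped`.
#' @export
make_anchors <- function(peaks, sizes = 9L, img_size = NULL, z = 1L) {
  stopif_not(length(sizes) > 0, "sizes must be non-empty")
  out <- bind_rows(lapply(sizes, function(s) {
    tibble(x = peaks$px - (s - 1) / 2, y = peaks$py - (s - 1) / 2,
           w = as.numeric(s), h = as.numeric(s), z = as.integer(z),
           px = peaks$px, py = peaks$py)
  }))
  out$clipped <- if (!is.null(img_size))
    out$x < 0 | out$y < 0 | out$x + out$w > img_size[1] |
      out$y + out$h > img_size[2] else FALSE
  out
}

# Bilinear interpolation matrix mapping a length-src axis to length-dst.
interp_matrix <- function(src, dst) {
  if (src == dst) return(diag(src))
  pos <- (seq_len(dst) - 0.5) * src / dst + 0.5   # in source pixel centres
  lo <- clamp(floor(pos), 1, src)
  hi <- clamp(lo + 1, 1, src)
  whi <- pos - lo
  M <- matrix(0, dst, src)
  for (i in seq_len(dst)) {
    M[i, lo[i]] <- M[i, lo[i]] + (1 - whi[i])
    M[i, hi[i]] <- M[i, hi[i]] + whi[i]
  }
  M
}

resize_mat <- function(m, dst) {
  L <- interp_matrix(nrow(m), dst)
  R <- interp_matrix(ncol(m), dst)
  L %*% m %*% t(R)
}

pad_center <- function(m, size) {
  s <- nrow(m)
  if (s == size) return(m)
  out <- matrix(0, size, size)
  off <- (size - s) %/% 2
  out[(off + 1):(off + s), (off + 1):(off + s)] <- m
  out
}

# Square crop of half-width hw centred at 0-based (cx, cy), zero-padded
# outside the frame.
crop_centered <- function(frame, cx, cy, hw) {
  H <- nrow(frame); W <- ncol(frame)
  s <- 2L * hw + 1L
  out <- matrix(0, s, s)
  ys <- (cy - hw):(cy + hw); xs <- (cx - hw):(cx + hw)
  iy <- ys >= 0 & ys < H; ix <- xs >= 0 & xs < W
  if (any(iy) && any(ix))
    out[which(iy), which(ix)] <- frame[ys[iy] + 1L, xs[ix] + 1L, drop = FALSE]
  out
}

#' Concentric multi-field crop around an anchor
#'
#' Builds the 5-channel 41 x 41 input patch of the detection network: the
#' anchor crop plus concentric fields of 15, 31, 41 and 81 pixels, all
#' centred on the anchor centre. Fields smaller than 41 are zero-padded to
#' 41; the 81 field is bilinearly resized down to 41. Pixel values are scaled
#' to `[0, 1]` by the frame maximum.
#'
#' @param frame `H x W` matrix.
#' @param anchor one-row tibble with `x, y, w, h` (an odd square box).
#' @param field_sizes the four context field sizes.
#' @param out_size output side length.
#' @return A `out_size x out_size x 5` array.
#' @export
crop_multifield <- function(frame, anchor, field_sizes = c(15, 31, 41, 81),
                            out_size = 41) {
  mx <- max(frame)
  f01 <- if (mx > 0) frame / mx else frame
  cx <- as.integer(round(anchor$x + (anchor$w - 1) / 2))
  cy <- as.integer(round(anchor$y + (anchor$h - 1) / 2))
  sizes <- c(anchor$w, field_sizes)
  out <- array(0, dim = c(out_size, out_size, length(sizes)))
  for (k in seq_along(sizes)) {
    s <- as.integer(sizes[k])
    crop <- crop_centered(f01, cx, cy, (s - 1L) %/% 2L)
    out[, , k] <- if (s <= out_size) pad_center(crop, out_size)
      else resize_mat(crop, out_size)
  }
  out
}

#' Bounding-box correction targets
#'
#' The dimensionless offsets and scale ratios that map an anchor onto its
#' ground-truth box: `dx = (xG - xA) / wA`, `dy = (yG - yA) / hA`,
#' `omega = wG / wA`, `eta = hG / hA`.
#'
#' @param anchor,gt one-row data frames with `x, y, w, h`.
#' @return A tibble `dx, dy, omega, eta`.
#' @seealso [apply_correction()], the exact inverse.
#' @export
correction_targets <- function(anchor, gt) {
  stopif_not(all(anchor$w > 0) && all(anchor$h > 0), "anchor sizes must be > 0")
  tibble(dx = (gt$x - anchor$x) / anchor$w,
         dy = (gt$y - anchor$y) / anchor$h,
         omega = gt$w / anchor$w,
         eta = gt$h / anchor$h)
}

#' Apply predicted corrections to an anchor
#'
#' Inverse of [correction_targets()]: `x = dx * wA + xA`, `y = dy * hA + yA`,
#' `w = omega * wA`, `h = eta * hA`, `z = zA`. Exact floats; any rounding to
#' pixel boxes happens only at final output.
#'
#' @param anchor data frame with `x, y, w, h` (and optionally `z`).
#' @param pred data frame with `dx, dy, omega, eta`.
#' @return A tibble `x, y, w, h, z`.
#' @export
apply_correction <- function(anchor, pred) {
  stopif_not(all(pred$omega > 0) && all(pred$eta > 0),
             "scale ratios must be positive")
  tibble(x = pred$dx * anchor$w + anchor$x,
         y = pred$dy * anchor$h + anchor$y,
         w = pred$omega * anchor$w,
         h = pred$eta * anchor$h,
         z = anchor[["z"]] %||% rep(1L, nrow(pred)))
}

#' Non-maximum suppression
#'
#' Drops regions scoring below `score_floor`, then greedily keeps the
#' highest-score region and suppresses any remaining region whose IoU with a
#' kept region exceeds `overlap_threshold`, independently per frame. Ties are
#' broken by (score desc, x, y).
#'
#' @param regions tibble with `x, y, w, h, z, score`.
#' @param score_floor minimum score (default 0.4).
#' @param overlap_threshold IoU above which a region is suppressed (0.20).
#' @return The surviving subset, ordered by (z, score desc, x, y).
#' @export
nms <- function(regions, score_floor = 0.4, overlap_threshold = 0.20) {
  regions <- filter(regions, score >= score_floor)
  if (nrow(regions) == 0) return(regions)
  out <- lapply(split(regions, regions$z), function(rs) {
    rs <- arrange(rs, desc(score), x, y)
    keep <- logical(nrow(rs))
    alive <- rep(TRUE, nrow(rs))
    for (i in seq_len(nrow(rs))) {
      if (!alive[i]) next
      keep[i] <- TRUE
      if (i < nrow(rs)) {
        rest <- (i + 1):nrow(rs)
        ov <- iou_box(rs$x[rest], rs$y[rest], rs$w[rest], rs$h[rest],
                      rs$x[i], rs$y[i], rs$w[i], rs$h[i])
        alive[rest][ov > overlap_threshold] <- FALSE
      }
    }
    rs[keep, ]
  })
  bind_rows(out)
}

#' Evaluate 2D detection against ground truth
#'
#' One-to-one greedy matching by descending IoU within each frame; a
#' predicted region matched to a ground-truth region with IoU above
#' `iou_threshold` is a true positive. Precision = TP / predictions,
#' recall = TP / ground truth, F1 = harmonic mean.
#'
#' @param pred,gt region tibbles with `x, y, w, h, z`.
#' @param iou_threshold match threshold (default 0.3).
#' @return A tibble `precision, recall, f1, tp, n_pred, n_gt`.
#' @export
evaluate_detection <- function(pred, gt, iou_threshold = 0.3) {
  stopif_not(nrow(gt) > 0, "empty ground truth: recall undefined")
  tp <- 0L
  for (zz in unique(gt$z)) {
    p <- pred[pred$z == zz, ]; g <- gt[gt$z == zz, ]
    if (nrow(p) == 0 || nrow(g) == 0) next
    wm <- iou_matrix(p, g)
    repeat {
      best <- which.max(wm)
      if (length(best) == 0 || wm[best] <= iou_threshold) break
      i <- (best - 1) %% nrow(wm) + 1; j <- (best - 1) %/% nrow(wm) + 1
      tp <- tp + 1L
      wm[i, ] <- -1; wm[, j] <- -1
    }
  }
  precision <- if (nrow(pred) > 0) tp / nrow(pred) else 0
  recall <- tp / nrow(gt)
  f1 <- if (precision + recall > 0) 2 * precision * recall /
    (precision + recall) else 0
  tibble(precision = precision, recall = recall, f1 = f1, tp = tp,
         n_pred = nrow(pred), n_gt = nrow(gt))
}
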