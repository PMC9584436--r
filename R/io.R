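#' Write / read an imaging volume as multi-page TIFF
#'
#' One 16-bit grayscale page per frame. Integer intensities in
#' `[0, 65535]` round-trip bit-identically.
#'
#' @param volume `H x W x Z` numeric array of integer-valued intensities.
#' @param path file path.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns the
#'   `H x W x Z` array.
#' @export
write_volume <- function(volume, path) {
  stopif_not(length(dim(volume)) == 3, "volume must be H x W x Z")
  stopif_not(all(volume >= 0 & volume <= 65535),
             "intensities must lie in [0, 65535]")
  pages <- lapply(seq_len(dim(volume)[3]), function(k) volume[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("mixed page sizes in TIFF volume")
  arr <- array(0, dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- round(pages[[k]] * 65535)
  arr
}

#' Write / read neuron annotations as JSON
#'
#' Schema: a top-level object with a `convention` field documenting the
#' coordinate system ("0-based pixel coordinates; boxes half-open
#' [x, x+w) x [y, y+h); z is the 1-based frame index") and a `volumes` array
#' of `{volume_index, regions: [{x, y, w, h, z, id}], objects: [{id,
#' region_indices, centroid}]}`. Region `id` is the digital ID (may be null);
#' `region_indices` are 1-based indices into the volume's region list.
#'
#' @param annotations a list of per-volume lists with elements
#'   `volume_index`, `regions` (tibble `x, y, w, h, z, id`), and optionally
#'   `objects` (tibble `id, cx, cy, cz` plus list-column `region_indices`).
#' @param path file path.
#' @return `write_annotations` returns `path` invisibly; `read_annotations`
#'   returns the annotations list with tibble elements.
#' @export
write_annotations <- function(annotations, path) {
  vols <- lapply(annotations, function(v) {
    out <- list(volume_index = v$volume_index,
                regions = as.data.frame(v$regions))
    if (!is.null(v$objects)) {
      out$objects <- lapply(seq_len(nrow(v$objects)), function(i) {
        o <- v$objects[i, ]
        list(id = o$id, region_indices = o$region_indices[[1]],
             centroid = c(o$cx, o$cy, o$cz))
      })
    }
    out
  })
  obj <- list(convention = paste("0-based pixel coordinates; boxes half-open",
                                 "[x, x+w) x [y, y+h); z is the 1-based",
                                 "frame index"),
              volumes = vols)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$volumes))
    abort(sprintf("%s: missing 'volumes' array", path))
  lapply(seq_along(obj$volumes), function(k) {
    v <- obj$volumes[[k]]
    if (is.null(v$volume_index))
      abort(sprintf("%s: volumes[%d]: missing volume_index", path, k))
    regions <- if (length(v$regions) == 0) {
      tibble(x = numeric(), y = numeric(), w = numeric(), h = numeric(),
             z = integer(), id = integer())
    } else {
      bad <- which(vapply(v$regions, function(r)
        !all(c("x", "y", "w", "h", "z") %in% names(r)), logical(1)))
      if (length(bad) > 0)
        abort(sprintf("%s: volumes[%d]: regions[%d] missing x/y/w/h/z",
                      path, k, bad[1]))
      bind_rows(lapply(v$regions, function(r)
        tibble(x = as.numeric(r$x), y = as.numeric(r$y),
               w = as.numeric(r$w), h = as.numeric(r$h),
               z = as.integer(r$z),
               id = if (is.null(r$id)) NA_integer_ else as.integer(r$id))))
    }
    objects <- NULL
    if (!is.null(v$objects) && length(v$objects) > 0) {
      objects <- bind_rows(lapply(v$objects, function(o)
        tibble(id = as.integer(o$id),
               region_indices = list(as.integer(unlist(o$region_indices))),
               cx = as.numeric(o$centroid[[1]]),
               cy = as.numeric(o$centroid[[2]]),
               cz = as.numeric(o$centroid[[3]]))))
    }
    list(volume_index = v$volume_index, regions = regions, objects = objects)
  })
}

# Export a synthetic dataset's ground truth to the annotation schema.
gt_to_annotations <- function(dataset) {
  lapply(dataset$volumes, function(v) {
    regions <- select(v$gt$regions, x, y, w, h, z, id)
    objs <- v$gt$objects
    region_indices <- lapply(objs$id, function(i)
      which(v$gt$regions$id == i))
    objects <- tibble(id = objs$id, region_indices = region_indices,
                      cx = objs$cx, cy = objs$cy, cz = objs$cz)
    list(volume_index = v$volume_index, regions = regions, objects = objects)
  })
}

#' Fit an affine red-to-green channel map
#'
#' Least-squares fit of the 2 x 3 affine transform mapping red-channel pixel
#' coordinates to green-channel coordinates from matched landmark pairs.
#'
#' @param red_points,green_points matrices / data frames of matched `(x, y)`
#'   coordinates.
#' @return A 2 x 3 matrix `M` so that `green = M %*% c(x, y, 1)`.
#' @export
fit_channel_map <- function(red_points, green_points) {
  red_points <- as.matrix(red_points); green_points <- as.matrix(green_points)
  A <- cbind(red_points[, 1], red_points[, 2], 1)
  t(qr.solve(A, green_points))  # 2 x 3
}

#' Identity channel map
#' @return The 2 x 3 identity affine.
#' @export
identity_channel_map <- function() cbind(diag(2), c(0, 0))

#' Extract ratiometric activity traces
#'
#' For every neuron object: `F_RFP` is the mean red intensity over the
#' object's member-region pixels; green pixels are sampled at the
#' affine-mapped coordinates (nearest pixel) to give `F_GCaMP`; the activity
#' is the ratio `R = F_GCaMP / F_RFP`. With `background_subtract = TRUE`
#' (default) a local background — the median intensity of an annulus of
#' width `annulus` pixels around each region, which captures diffuse
#' autofluorescence under the neuron — is subtracted from each channel's
#' mean before the ratio. Objects whose mapped region falls outside the
#' green frame are flagged `missing` rather than zeroed.
#'
#' @param regions region tibble with `object_id` (e.g. from
#'   [merge_regions()]).
#' @param red,green `H x W x Z` arrays of the two channels.
#' @param map 2 x 3 affine red-to-green map (default identity).
#' @param background_subtract subtract the local annulus background?
#' @param annulus width (px) of the background annulus around each region.
#' @return A tibble `object_id, F_R, F_G, R, flag` of class `wt_traces`.
#' @export
extract_activity <- function(regions, red, green,
                             map = identity_channel_map(),
                             background_subtract = TRUE, annulus = 5) {
  stopif_not(all(dim(red) == dim(green)), "channel shapes must match")
  H <- dim(red)[1]; W <- dim(red)[2]
  box_pixels <- function(x, y, w, h) {
    x0 <- max(0, floor(x)); y0 <- max(0, floor(y))
    x1 <- min(W - 1, ceiling(x + w) - 1); y1 <- min(H - 1, ceiling(y + h) - 1)
    if (x1 < x0 || y1 < y0) return(NULL)
    cbind(gx = rep(x0:x1, each = y1 - y0 + 1),
          gy = rep(y0:y1, times = x1 - x0 + 1))
  }
  sample_green <- function(px, zf) {
    mapped <- map %*% rbind(px[, "gx"], px[, "gy"], 1)
    mx <- round(mapped[1, ]); my <- round(mapped[2, ])
    ok <- mx >= 0 & mx < W & my >= 0 & my < H
    list(vals = green[cbind(my[ok] + 1, mx[ok] + 1, rep(zf, sum(ok)))],
         all_in = all(ok))
  }
  out <- lapply(sort(unique(regions$object_id)), function(oid) {
    rr <- regions[regions$object_id == oid, ]
    fr_vals <- numeric(); fg_vals <- numeric(); miss <- FALSE
    bgr_vals <- numeric(); bgg_vals <- numeric()
    for (i in seq_len(nrow(rr))) {
      px <- box_pixels(rr$x[i], rr$y[i], rr$w[i], rr$h[i])
      if (is.null(px)) next
      fr_vals <- c(fr_vals, red[cbind(px[, "gy"] + 1, px[, "gx"] + 1,
                                      rep(rr$z[i], nrow(px)))])
      sg <- sample_green(px, rr$z[i])
      if (!sg$all_in) miss <- TRUE
      fg_vals <- c(fg_vals, sg$vals)
      if (background_subtract) {
        big <- box_pixels(rr$x[i] - annulus, rr$y[i] - annulus,
                          rr$w[i] + 2 * annulus, rr$h[i] + 2 * annulus)
        inner <- paste(px[, "gx"], px[, "gy"])
        ring <- big[!(paste(big[, "gx"], big[, "gy"]) %in% inner), ,
                    drop = FALSE]
        if (nrow(ring) > 0) {
          bgr_vals <- c(bgr_vals, red[cbind(ring[, "gy"] + 1,
                                            ring[, "gx"] + 1,
                                            rep(rr$z[i], nrow(ring)))])
          bgg_vals <- c(bgg_vals, sample_green(ring, rr$z[i])$vals)
        }
      }
    }
    if (length(fr_vals) == 0 || length(fg_vals) == 0)
      return(tibble(object_id = oid, F_R = NA_real_, F_G = NA_real_,
                    R = NA_real_, flag = "missing"))
    F_R <- mean(fr_vals) -
      (if (length(bgr_vals) > 0) median(bgr_vals) else 0)
    F_G <- mean(fg_vals) -
      (if (length(bgg_vals) > 0) median(bgg_vals) else 0)
    R <- if (F_R > 0) F_G / F_R else NA_real_
    tibble(object_id = oid, F_R = F_R, F_G = F_G, R = R,
           flag = if (miss) "missing" else if (F_R <= 0) "nonpositive_ref"
           else "ok")
  })
  out <- bind_rows(out)
  class(out) <- c("wt_traces", class(out))
  out
}
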