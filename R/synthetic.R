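#' Specify a synthetic worm-head layout
#'
#' Defines the study conditions for the synthetic 4D volume generator: a
#' worm-head-shaped ellipsoidal cluster of nucleus-like fluorescent blobs that
#' is rigidly moved and smoothly bent between volumes, with in-plane drift of
#' the whole layout during each Z-scan and additive Gaussian background noise.
#' Every downstream stage (head segmentation, region detection, 3D merging,
#' identity recognition, activity extraction) can be trained and tested
#' against the generator's exact ground truth.
#'
#' @param n_neurons number of nucleus-like blobs (>= 1).
#' @param img_size image size in pixels, `c(width, height)`.
#' @param z_extent number of frames per volume.
#' @param head_axes ellipse semi-axes of the head in pixels,
#'   `c(semi_major, semi_minor)`; the major axis is the canonical
#'   anterior-posterior axis.
#' @param head_center head centre in pixel coordinates `c(x, y)`.
#' @param blob_radius_range min/max blob radius in pixels; radius drives both
#'   the lateral Gaussian width (sd = radius / 2) and the axial span
#'   (1-4 consecutive frames, larger nuclei spanning more frames).
#' @param intensity_range min/max peak grayscale amplitude of a blob.
#' @param background_level,background_noise_sigma mean and sd of the additive
#'   Gaussian background.
#' @param head_glow peak amplitude of a dim head-shaped autofluorescence
#'   smear rendered under the nuclei (it follows the volume's rigid pose),
#'   emulating diffuse neuropil fluorescence that makes the head appear as
#'   one connected region.
#' @param interframe_shift_px maximum in-plane shift (per axis, px) of the
#'   whole layout between consecutive frames of one volume; shifts accumulate
#'   across the Z-scan, emulating motion during acquisition.
#' @param intervolume_bend list with `max_bend_deg` (relative rotation of the
#'   anterior vs posterior half), `max_rot_deg` and `max_shift_px` (rigid pose
#'   change between volumes).
#' @param exclusion_radius minimum in-plane distance between blob centres (px).
#' @param body if `TRUE`, a dim elongated body-shaped smear is rendered
#'   outside the head so head segmentation has a non-head region to reject.
#' @param seed integer seed; all randomness of the generator derives from it.
#'
#' @return An object of class `layout_spec`.
#' @seealso [synth_preset()], [generate_layout()], [generate_dataset()]
#' @export
layout_spec <- function(n_neurons = 60,
                        img_size = c(256, 256),
                        z_extent = 12,
                        head_axes = c(75, 40),
                        head_center = c(140, 128),
                        blob_radius_range = c(2, 4),
                        intensity_range = c(120, 240),
                        background_level = 10,
                        background_noise_sigma = 6,
                        head_glow = 45,
                        interframe_shift_px = 2,
                        intervolume_bend = list(max_bend_deg = 30,
                                                max_rot_deg = 20,
                                                max_shift_px = 12),
                        exclusion_radius = 6,
                        body = TRUE,
                        seed = 0L) {
  stopif_not(n_neurons >= 1, "n_neurons must be >= 1")
  stopif_not(z_extent >= 1, "z_extent must be >= 1")
  stopif_not(blob_radius_range[1] <= blob_radius_range[2] &&
               blob_radius_range[1] > 0, "invalid blob_radius_range")
  spec <- list(n_neurons = as.integer(n_neurons), img_size = img_size,
               z_extent = as.integer(z_extent), head_axes = head_axes,
               head_center = head_center,
               blob_radius_range = blob_radius_range,
               intensity_range = intensity_range,
               background_level = background_level,
               background_noise_sigma = background_noise_sigma,
               head_glow = head_glow,
               interframe_shift_px = interframe_shift_px,
               intervolume_bend = intervolume_bend,
               exclusion_radius = exclusion_radius,
               body = body, seed = as.integer(seed))
  structure(spec, class = "layout_spec")
}

#' Preset synthetic regimes
#'
#' `"easy"` is the default desk-scale regime (256 x 256 x 12 voxels, 60
#' neurons, interframe drift <= 2 px); `"hard"` is denser and more deformed
#' (512 x 512 x 18, 150 neurons, drift <= 4 px, 45 degree bends).
#'
#' @param preset `"easy"` or `"hard"`.
#' @param seed integer seed.
#' @param ... overrides passed on to [layout_spec()].
#' @return A `layout_spec`.
#' @export
synth_preset <- function(preset = c("easy", "hard"), seed = 0L, ...) {
  preset <- match.arg(preset)
  if (preset == "easy") return(layout_spec(seed = seed, ...))
  layout_spec(n_neurons = 150, img_size = c(512, 512), z_extent = 18,
              head_axes = c(130, 70), head_center = c(280, 256),
              interframe_shift_px = 4,
              intervolume_bend = list(max_bend_deg = 45, max_rot_deg = 30,
                                      max_shift_px = 24),
              exclusion_radius = 6, seed = seed, ...)
}

# Axial span (frames) of a blob grows with its radius: the nucleus size in
# X-Y correlates strongly with its size along Z.
blob_z_span <- function(r, rng) {
  frac <- (r - rng[1]) / max(rng[2] - rng[1], 1e-9)
  pmin(4L, pmax(1L, as.integer(round(1 + frac * 3))))
}

# Rendered lateral support half-width: widths 7/9/11 px across the default
# radius range, matching the ~9 px nucleus scale.
blob_halfwidth <- function(r) pmax(3L, as.integer(ceiling(1.1 * r)))

#' Generate the canonical neuron layout
#'
#' Places `n_neurons` blob centres inside the ellipsoidal head with a minimum
#' pairwise in-plane distance (dart throwing with bounded retries), a mild
#' anterior and ventral density/intensity bias (so the intrinsic coordinate
#' axes are recoverable from the images), and per-blob radius, peak intensity
#' and axial span. Deterministic given `spec$seed`.
#'
#' @param spec a [layout_spec()].
#' @return A tibble with one row per neuron: `id`, canonical head-local
#'   coordinates `x`, `y` (px, anterior = +x, ventral = +y), axial centre `z`
#'   (frame units), `radius`, `intensity`, `z_span`.
#' @export
generate_layout <- function(spec) {
  stopif_not(inherits(spec, "layout_spec"), "spec must be a layout_spec")
  a <- spec$head_axes[1]; b <- spec$head_axes[2]
  Z <- spec$z_extent
  zc <- (Z + 1) / 2; zr <- max((Z - 1) / 2 * 0.8, 0.01)
  n <- spec$n_neurons
  excl2 <- spec$exclusion_radius^2
  with_seed(spec$seed, {
    xs <- numeric(n); ys <- numeric(n); zs <- numeric(n)
    placed <- 0L
    tries <- 0L; max_tries <- 500L * n
    # Mimic head-ganglion anatomy: ~40% of nuclei form a dense, bright
    # anterior-ventral cluster (the nerve-ring analogue), ~20% a ventral
    # line running posteriorly (the ventral-cord analogue), the rest spread
    # symmetrically. The anterior cluster plus the ventral band is what lets
    # the coordinate-system builder orient both axes from point-of-interest
    # counts: more bright pixels lie anterior and ventral of the centre of
    # mass in every pose.
    role_draw <- runif(n)
    role <- ifelse(role_draw < 0.4, 1L, ifelse(role_draw < 0.6, 2L, 3L))
    cons_fail <- 0L   # after many failures in a row, widen to diffuse
    while (placed < n && tries < max_tries) {
      tries <- tries + 1L
      r_i <- if (cons_fail < 200L) role[placed + 1L] else 3L
      if (r_i == 1L) {            # nerve-ring cluster: anterior-ventral
        u <- rnorm(1, 0.5, 0.2)
        v <- rnorm(1, 0.5, 0.22)
      } else if (r_i == 2L) {     # ventral cord: posterior-ventral band
        u <- runif(1, -0.85, -0.05)
        v <- rnorm(1, 0.55, 0.1)
      } else {                    # diffuse
        u <- runif(1, -1, 1)
        v <- runif(1, -1, 1)
      }
      zeta <- runif(1, -1, 1)
      if (u^2 + v^2 + zeta^2 > 1) next
      x <- u * a; y <- v * b; z <- zc + zeta * zr
      if (placed > 0L) {
        d2 <- (xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2
        if (min(d2) < excl2) { cons_fail <- cons_fail + 1L; next }
      }
      placed <- placed + 1L
      cons_fail <- 0L
      xs[placed] <- x; ys[placed] <- y; zs[placed] <- z
    }
    if (placed < n)
      abort(sprintf(
        "could not place %d neurons at exclusion radius %.1f px (placed %d)",
        n, spec$exclusion_radius, placed))
    radius <- runif(n, spec$blob_radius_range[1], spec$blob_radius_range[2])
    base_int <- runif(n, spec$intensity_range[1], spec$intensity_range[2])
    # the bright on-axis cluster dominates the intensity-weighted centre of
    # mass (pulling it along, not across, the body axis); cord and diffuse
    # nuclei stay dim so the ventral bias is a count, not a mass, asymmetry
    grad <- c(1.25, 1.15, 0.85)[role[seq_len(n)]]
    intensity <- clamp(base_int * grad,
                       spec$intensity_range[1], spec$intensity_range[2])
    tibble(id = seq_len(n), x = xs, y = ys, z = zs, radius = radius,
           intensity = intensity,
           z_span = blob_z_span(radius, spec$blob_radius_range))
  })
}

#' Deform the canonical layout into one volume's pose
#'
#' Applies a smooth bending field (the anterior and posterior halves of the
#' head end up rotated relative to each other by the drawn bend angle, with a
#' narrow smooth transition zone around the head centre) followed by a rigid
#' in-plane rotation and translation. Pose parameters are drawn uniformly
#' within the bounds in `spec$intervolume_bend`, deterministically per
#' `(spec$seed, volume_index)`.
#'
#' @param layout tibble from [generate_layout()].
#' @param volume_index positive integer volume (time point) index.
#' @param spec the [layout_spec()].
#' @param pose optional list with `bend_deg`, `rot_deg`, `shift` to impose a
#'   fixed pose instead of drawing one.
#' @return A list with `points` (tibble `id, x, y, z` in image pixel
#'   coordinates) and `pose` (true worm-frame pose: `origin`, unit `ap` and
#'   `vd` axis vectors of the rigid part, plus the drawn parameters).
#' @export
deform_layout <- function(layout, volume_index, spec, pose = NULL) {
  iv <- spec$intervolume_bend
  if (is.null(pose)) {
    pose <- with_seed(child_seed(spec$seed, volume_index, 1L), {
      list(bend_deg = runif(1, -iv$max_bend_deg, iv$max_bend_deg),
           rot_deg = runif(1, -iv$max_rot_deg, iv$max_rot_deg),
           shift = runif(2, -iv$max_shift_px, iv$max_shift_px))
    })
  }
  beta <- pose$bend_deg * pi / 180
  theta <- pose$rot_deg * pi / 180
  a <- spec$head_axes[1]
  wtrans <- 0.2 * a
  # bend: rotate each point about the head centre by alpha(x), ramping from
  # -beta/2 (posterior) to +beta/2 (anterior) across the transition zone
  alpha <- beta * clamp(layout$x / (2 * wtrans), -0.5, 0.5)
  xb <- cos(alpha) * layout$x - sin(alpha) * layout$y
  yb <- sin(alpha) * layout$x + cos(alpha) * layout$y
  ct <- cos(theta); st <- sin(theta)
  ox <- spec$head_center[1] + pose$shift[1]
  oy <- spec$head_center[2] + pose$shift[2]
  pts <- tibble(id = layout$id,
                x = ct * xb - st * yb + ox,
                y = st * xb + ct * yb + oy,
                z = layout$z)
  pose$origin <- c(ox, oy)
  pose$ap <- c(ct, st)
  pose$vd <- c(-st, ct)
  list(points = pts, pose = pose)
}

# Render one Gaussian-profile blob into a frame matrix (in place semantics:
# returns the modified matrix). Centre (cx, cy) is 0-based pixel coords.
render_blob <- function(frame, cx, cy, sdv, amp, hw) {
  H <- nrow(frame); W <- ncol(frame)
  x0 <- max(0L, as.integer(round(cx)) - hw)
  x1 <- min(W - 1L, as.integer(round(cx)) + hw)
  y0 <- max(0L, as.integer(round(cy)) - hw)
  y1 <- min(H - 1L, as.integer(round(cy)) + hw)
  if (x1 < x0 || y1 < y0) return(frame)
  gx <- exp(-((x0:x1) - cx)^2 / (2 * sdv^2))
  gy <- exp(-((y0:y1) - cy)^2 / (2 * sdv^2))
  frame[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <-
    frame[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] + amp * outer(gy, gx)
  frame
}

# Axial intensity taper across a blob's z-span: peaked at the span centre,
# monotone toward both ends, so a single nucleus never shows an interior
# intensity minimum (that signature is reserved for fused neighbours).
axial_taper <- function(frames) {
  s <- length(frames)
  if (s == 1L) return(1)
  mid <- (frames[1] + frames[s]) / 2
  1 - 0.35 * abs(frames - mid) / ((s - 1) / 2)
}

#' Render a posed layout into an imaging volume with ground truth
#'
#' Each blob is rendered as a Gaussian-profile disc on the consecutive frames
#' its axial span covers, with an axial intensity taper. The whole layout
#' additionally drifts in-plane during the Z-scan: a cumulative per-frame
#' shift of at most `interframe_shift_px` per axis. Additive Gaussian
#' background noise (plus an optional dim body smear) completes the image;
#' intensities are clamped at zero and rounded to integers so volumes
#' round-trip losslessly through 16-bit TIFF.
#'
#' @param posed result of [deform_layout()].
#' @param spec the [layout_spec()].
#' @param volume_index volume index (drives the render RNG stream).
#' @param layout the canonical layout (for radius/intensity/span).
#' @param activity optional numeric vector (one multiplier per neuron); when
#'   given, a green activity channel is rendered with blob amplitudes scaled
#'   by it.
#' @return A list: `red` (H x W x Z array), `green` (or `NULL`), `regions`
#'   (ground-truth tibble `id, x, y, w, h, z` of tight per-frame boxes),
#'   `shifts` (Z x 2 cumulative in-plane shift), `pose`.
#' @export
render_volume <- function(posed, spec, volume_index = 1L, layout,
                          activity = NULL) {
  W <- spec$img_size[1]; H <- spec$img_size[2]; Z <- spec$z_extent
  pts <- posed$points
  with_seed(child_seed(spec$seed, volume_index, 2L), {
    steps <- matrix(runif(2 * Z, -spec$interframe_shift_px,
                          spec$interframe_shift_px), ncol = 2)
    steps[1, ] <- 0
    shifts <- apply(steps, 2, cumsum)
    if (Z == 1L) shifts <- matrix(shifts, ncol = 2)

    base <- matrix(0, H, W)
    glow <- spec$head_glow %||% 0
    if (glow > 0) {
      ct0 <- posed$pose$ap[1]; st0 <- posed$pose$ap[2]
      ox0 <- posed$pose$origin[1]; oy0 <- posed$pose$origin[2]
      X <- matrix(rep(0:(W - 1), each = H), H, W)
      Y <- matrix(rep(0:(H - 1), times = W), H, W)
      u <- ct0 * (X - ox0) + st0 * (Y - oy0)
      v <- -st0 * (X - ox0) + ct0 * (Y - oy0)
      sa <- 0.7 * spec$head_axes[1]; sb <- 0.7 * spec$head_axes[2]
      base <- base + glow * exp(-(u^2 / (2 * sa^2) + v^2 / (2 * sb^2)))
    }
    if (isTRUE(spec$body)) {
      sc <- spec$img_size / c(256, 256)
      base <- render_blob(base, 30 * sc[1], 95 * sc[2], 14 * mean(sc),
                          45, as.integer(30 * mean(sc)))
    }

    red <- array(0, dim = c(H, W, Z))
    green <- if (!is.null(activity)) array(0, dim = c(H, W, Z)) else NULL
    gt <- vector("list", nrow(pts))

    hw <- blob_halfwidth(layout$radius)
    f0 <- as.integer(round(pts$z)) - (layout$z_span - 1L) %/% 2L
    f0 <- clamp(f0, 1L, Z - layout$z_span + 1L)

    for (zf in seq_len(Z)) {
      fr <- base + matrix(rnorm(H * W, spec$background_level,
                                spec$background_noise_sigma), H, W)
      fg <- if (!is.null(green))
        base + matrix(rnorm(H * W, spec$background_level,
                            spec$background_noise_sigma), H, W)
      for (i in seq_len(nrow(pts))) {
        if (zf < f0[i] || zf > f0[i] + layout$z_span[i] - 1L) next
        frames_i <- f0[i]:(f0[i] + layout$z_span[i] - 1L)
        taper <- axial_taper(frames_i)[match(zf, frames_i)]
        cx <- pts$x[i] + shifts[zf, 1]
        cy <- pts$y[i] + shifts[zf, 2]
        amp <- layout$intensity[i] * taper
        fr <- render_blob(fr, cx, cy, layout$radius[i] / 2, amp, hw[i])
        if (!is.null(green))
          fg <- render_blob(fg, cx, cy, layout$radius[i] / 2,
                            amp * activity[i], hw[i])
        gt[[i]][[length(gt[[i]]) + 1L]] <-
          c(id = pts$id[i],
            x = max(0L, as.integer(round(cx)) - hw[i]),
            y = max(0L, as.integer(round(cy)) - hw[i]),
            z = zf, hwp = hw[i],
            cx0 = as.integer(round(cx)), cy0 = as.integer(round(cy)))
      }
      red[, , zf] <- round(pmax(fr, 0))
      if (!is.null(green)) green[, , zf] <- round(pmax(fg, 0))
    }

    rows <- do.call(rbind, lapply(gt, function(g) do.call(rbind, g)))
    rows <- as_tibble(as.data.frame(rows))
    regions <- tibble(
      id = as.integer(rows$id),
      x = as.numeric(rows$x), y = as.numeric(rows$y),
      w = as.numeric(pmin(rows$cx0 + rows$hwp, W - 1L) - rows$x + 1L),
      h = as.numeric(pmin(rows$cy0 + rows$hwp, H - 1L) - rows$y + 1L),
      z = as.integer(rows$z))
    regions <- arrange(regions, z, x, y)
    list(red = red, green = green, regions = regions, shifts = shifts,
         pose = posed$pose)
  })
}

# Summarise ground-truth regions into per-neuron 3D objects.
gt_objects_from_regions <- function(regions) {
  regions |>
    mutate(cx = x + w / 2, cy = y + h / 2) |>
    group_by(id) |>
    summarise(n_regions = n(), z_start = min(z), z_end = max(z),
              cx = mean(cx), cy = mean(cy), cz = mean(z), .groups = "drop")
}

#' Generate a ground-truthed synthetic 4D dataset
#'
#' One canonical layout (one "animal"), independently deformed and rendered
#' per volume. Digital IDs are the layout row indices and are therefore
#' consistent across volumes. With `green = TRUE`, per-neuron smoothly varying
#' activity multipliers are generated, rendered into a green channel, and
#' recorded as ground truth.
#'
#' @param n_volumes number of volumes (>= 1).
#' @param spec a [layout_spec()].
#' @param green render an activity (green) channel?
#' @return A list of class `synth_dataset`: `volumes` (each with `red`,
#'   `green`, `gt = list(regions, objects, pose)`, `volume_index`), `layout`,
#'   `spec`, and `activity` (tibble `volume, id, activity`, or `NULL`).
#' @export
generate_dataset <- function(n_volumes, spec, green = FALSE) {
  stopif_not(n_volumes >= 1, "n_volumes must be >= 1")
  layout <- generate_layout(spec)
  act <- NULL
  if (green) {
    act <- with_seed(child_seed(spec$seed, 0L, 3L), {
      n <- nrow(layout)
      A <- runif(n, 0.2, 0.6); P <- runif(n, 8, 40); ph <- runif(n, 0, 2 * pi)
      do.call(rbind, lapply(seq_len(n_volumes), function(v)
        tibble(volume = v, id = layout$id,
               activity = exp(A * sin(2 * pi * v / P + ph)))))
    })
  }
  vols <- lapply(seq_len(n_volumes), function(v) {
    posed <- deform_layout(layout, v, spec)
    a_v <- if (green) act$activity[act$volume == v] else NULL
    r <- render_volume(posed, spec, v, layout, activity = a_v)
    list(red = r$red, green = r$green,
         gt = list(regions = r$regions,
                   objects = gt_objects_from_regions(r$regions),
                   pose = r$pose, shifts = r$shifts),
         volume_index = v)
  })
  structure(list(volumes = vols, layout = layout, spec = spec,
                 activity = act),
            class = "synth_dataset")
}
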