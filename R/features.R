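#' Cylindrical neuronal-density feature
#'
#' Counts neighbouring neuronal points in a sequence of q nested cylinders
#' around the target neuron, in worm coordinates with the origin at the
#' target centroid. Cylinder t has radius `t * dl` and half-height
#' `t * dz / 2`; bin t counts the points in cylinder t but not in cylinder
#' t - 1 (nested set difference), split into 4 territories: ventral
#' (`phi` in `[-pi/2, pi/2]`) vs dorsal, crossed with axial side
#' (`z >= 0` vs `z < 0`). The total over all bins therefore equals the number
#' of context points inside the outermost cylinder.
#'
#' @param target length-3 numeric `c(x, y, z)` centroid of the target neuron
#'   (pixel / frame units).
#' @param context data frame of context points with `x, y, z` columns; must
#'   exclude the target's own regions/object.
#' @param frame a `worm_frame`.
#' @param q number of nested cylinders (>= 1).
#' @param dl radial increment (px).
#' @param dz axial increment (frame units times `z_scale`).
#' @param z_scale axial scale applied to frame offsets.
#' @return A named numeric vector of length `q * 4`, ordered
#'   `t1_zplus_V, t1_zminus_V, t1_zplus_D, t1_zminus_D, t2_...`; attribute
#'   `"bins"` records `(q, dl, dz)`.
#' @export
density_feature <- function(target, context, frame, q = 8, dl = 10,
                            dz = NULL, z_scale = 1) {
  stopif_not(q >= 1, "q must be >= 1")
  stopif_not(dl > 0 && (is.null(dz) || dz > 0), "dl and dz must be positive")
  dz <- dz %||% 1
  nm <- as.vector(outer(c("zplus_V", "zminus_V", "zplus_D", "zminus_D"),
                        seq_len(q), function(s, t) paste0("t", t, "_", s)))
  counts <- setNames(numeric(4 * q), nm)
  if (nrow(context) > 0) {
    wc <- to_worm_coords(context, frame, z_scale = z_scale, origin = target)
    ventral <- wc$phi <= pi / 2            # phi in [-pi/2, pi/2]
    zplus <- wc$z >= 0
    terr <- ifelse(ventral, ifelse(zplus, 1L, 2L), ifelse(zplus, 3L, 4L))
    # cumulative in-cylinder membership, then successive differences
    incyl <- vapply(seq_len(q), function(t)
      wc$rho <= t * dl & abs(wc$z) <= t * dz / 2, logical(nrow(wc)))
    incyl <- matrix(incyl, nrow = nrow(wc))
    for (t in seq_len(q)) {
      inner <- if (t == 1) rep(FALSE, nrow(wc)) else incyl[, t - 1]
      sel <- incyl[, t] & !inner
      if (any(sel))
        counts[(t - 1) * 4 + seq_len(4)] <-
          counts[(t - 1) * 4 + seq_len(4)] + tabulate(terr[sel], 4)
    }
  }
  attr(counts, "bins") <- c(q = q, dl = dl, dz = dz)
  counts
}

#' K-nearest-neighbour positional feature
#'
#' Cylindrical worm coordinates `(rho, phi, z)` of the K nearest context
#' neuron objects, ordered by ascending 3D Euclidean distance from the target
#' centroid (ties broken by context row index). If fewer than K context
#' objects exist, the vector is padded with `(0, 0, 0)` sentinels and the pad
#' count recorded as an attribute.
#'
#' @inheritParams density_feature
#' @param K number of neighbours.
#' @return A numeric vector `rho_1, phi_1, z_1, ..., rho_K, phi_K, z_K` with
#'   attribute `"n_padded"`.
#' @export
knn_feature <- function(target, context, frame, K = 25, z_scale = 1) {
  stopif_not(nrow(context) >= 1, "empty context")
  wc <- to_worm_coords(context, frame, z_scale = z_scale, origin = target)
  d <- sqrt(wc$x_ap^2 + wc$y_vd^2 + wc$z^2)
  ord <- order(d, seq_along(d))
  take <- head(ord, K)
  trip <- rbind(wc$rho[take], wc$phi[take], wc$z[take])
  n_pad <- K - length(take)
  if (n_pad > 0) trip <- cbind(trip, matrix(0, 3, n_pad))
  out <- as.vector(trip)
  names(out) <- as.vector(outer(c("rho", "phi", "z"), seq_len(K),
                                function(a, k) paste0(a, k)))
  attr(out, "n_padded") <- n_pad
  out
}

#' Build recognition features for every neuron object in a volume
#'
#' For each object the density feature (context: all other objects'
#' centroids, or all 2D regions outside the object when
#' `source_mode = "regions"`) and the KNN feature (context: other objects)
#' are computed in worm coordinates centred on the object and concatenated.
#' Features depend only on relative positions in the worm frame, so they are
#' invariant to rigid motion of the volume.
#'
#' @param objects object tibble (from [merge_regions()] or ground truth) with
#'   `object_id` (or `id`), `cx, cy, cz`.
#' @param frame a `worm_frame`.
#' @param q,dl,dz,K,z_scale feature parameters; `dl` defaults to the head
#'   semi-major length / q, `dz` to `depth * z_scale / q`.
#' @param depth volume depth in frames (required unless `dz` given).
#' @param source_mode `"regions"` uses 2D region centres as density context
#'   (requires `regions` with `x, y, w, h, z, object_id`); `"objects"` uses
#'   object centroids.
#' @param regions region tibble when `source_mode = "regions"`.
#' @return A tibble `object_id` plus one list-free numeric column per feature
#'   dimension is avoided: instead a tibble with `object_id` and a `feature`
#'   list-column; use [feature_matrix()] to get the dense matrix. The feature
#'   configuration is stored in attribute `"feature_config"`.
#' @export
featurize_volume <- function(objects, frame, q = 8, dl = NULL, dz = NULL,
                             K = 25, z_scale = 1, depth = NULL,
                             source_mode = c("objects", "regions"),
                             regions = NULL) {
  source_mode <- match.arg(source_mode)
  if ("id" %in% names(objects) && !"object_id" %in% names(objects))
    objects <- dplyr::rename(objects, object_id = id)
  if (is.null(dl)) {
    ap_len <- (sqrt(sum((frame$P_a - frame$O)^2)) +
                 sqrt(sum((frame$P_p - frame$O)^2))) / 2
    dl <- ap_len / q
  }
  if (is.null(dz)) {
    stopif_not(!is.null(depth), "need depth (frames) or dz")
    dz <- depth * z_scale / q
  }
  if (source_mode == "regions") stopif_not(!is.null(regions),
                                           "regions required in regions mode")
  cents <- tibble(x = objects$cx, y = objects$cy, z = objects$cz)
  feats <- vector("list", nrow(objects))
  for (i in seq_len(nrow(objects))) {
    target <- c(objects$cx[i], objects$cy[i], objects$cz[i])
    ctx_obj <- cents[-i, , drop = FALSE]
    dens_ctx <- if (source_mode == "objects") ctx_obj else {
      rr <- regions[regions$object_id != objects$object_id[i], ]
      tibble(x = rr$x + rr$w / 2, y = rr$y + rr$h / 2, z = as.numeric(rr$z))
    }
    fden <- density_feature(target, dens_ctx, frame, q = q, dl = dl, dz = dz,
                            z_scale = z_scale)
    fknn <- if (nrow(ctx_obj) >= 1)
      knn_feature(target, ctx_obj, frame, K = K, z_scale = z_scale)
    else setNames(numeric(3 * K), as.vector(outer(c("rho", "phi", "z"),
                                                  seq_len(K), paste0)))
    feats[[i]] <- c(fden, fknn)
  }
  out <- tibble(object_id = objects$object_id, feature = feats)
  attr(out, "feature_config") <- list(q = q, dl = dl, dz = dz, K = K,
                                      z_scale = z_scale,
                                      source_mode = source_mode)
  out
}

#' Dense feature matrix from a feature tibble
#'
#' @param features tibble from [featurize_volume()] (rows may come from
#'   several volumes via `bind_rows`).
#' @return Numeric matrix, one row per neuron.
#' @export
feature_matrix <- function(features) {
  do.call(rbind, lapply(features$feature, as.numeric))
}
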