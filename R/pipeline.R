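#' Match predicted objects to ground-truth objects
#'
#' Greedy one-to-one matching by ascending centroid distance (lateral px,
#' with the axial offset scaled by `z_weight` px per frame); matches beyond
#' `max_dist` are left unlabelled. Used to give detected objects their true
#' digital IDs for evaluation.
#'
#' @param pred_objects tibble with `object_id, cx, cy, cz`.
#' @param gt_objects tibble with `id, cx, cy, cz`.
#' @param max_dist maximum centroid distance for a valid match (px).
#' @param z_weight axial scaling (px per frame).
#' @return `pred_objects` with an added `true_id` column (`NA` if unmatched).
#' @export
label_objects <- function(pred_objects, gt_objects, max_dist = 6,
                          z_weight = 4) {
  np <- nrow(pred_objects); ng <- nrow(gt_objects)
  true_id <- rep(NA_integer_, np)
  if (np > 0 && ng > 0) {
    D <- outer(pred_objects$cx, gt_objects$cx, "-")^2 +
      outer(pred_objects$cy, gt_objects$cy, "-")^2 +
      (z_weight * outer(pred_objects$cz, gt_objects$cz, "-"))^2
    D <- sqrt(D)
    ord <- order(D)
    used_p <- logical(np); used_g <- logical(ng)
    for (k in ord) {
      if (D[k] > max_dist) break
      i <- (k - 1) %% np + 1; j <- (k - 1) %/% np + 1
      if (used_p[i] || used_g[j]) next
      used_p[i] <- TRUE; used_g[j] <- TRUE
      true_id[i] <- gt_objects$id[j]
    }
  }
  mutate(pred_objects, true_id = true_id)
}

#' Run the full pipeline on a set of volumes
#'
#' Per volume, independently (the method is sequence-independent):
#' pre-processing (head segmentation + worm frame), region detection, 3D
#' merging, feature engineering, digital-ID assignment, and — when a green
#' channel is present — ratiometric activity extraction. Per-volume failures
#' are isolated and reported in the `errors` element without aborting the
#' batch.
#'
#' @param volumes list of volumes; each element either an `H x W x Z` array
#'   (red channel) or a list with `red` and optional `green` arrays.
#' @param detector a `wt_detector`.
#' @param recognizer a `wt_recognizer`, or `NULL` to stop after merging.
#' @param channel_map 2 x 3 affine red-to-green map.
#' @param q,K,z_scale feature settings (must match recognizer training).
#' @param source_mode density-feature context mode.
#' @return A list of class `wt_pipeline_result`: `objects` (tibble over all
#'   volumes with `volume, object_id, ...` and `assigned_id`), `regions`,
#'   `traces` (or `NULL`), `timing` (per-stage seconds per volume), `errors`,
#'   `config_hash`.
#' @export
run_pipeline <- function(volumes, detector, recognizer = NULL,
                         channel_map = identity_channel_map(),
                         q = 8, K = 25, z_scale = 1,
                         source_mode = "regions") {
  cfg <- list(q = q, K = K, z_scale = z_scale, source_mode = source_mode,
              anchor_sizes = detector$anchor_sizes)
  cfg_hash <- rlang::hash(cfg)
  all_objects <- list(); all_regions <- list(); all_traces <- list()
  errors <- list(); timing <- list()
  for (v in seq_along(volumes)) {
    vol <- volumes[[v]]
    red <- if (is.list(vol)) vol$red else vol
    green <- if (is.list(vol)) vol$green else NULL
    res <- tryCatch({
      tm <- c(pre = 0, detect = 0, merge = 0, feat = 0, id = 0, act = 0)
      t0 <- proc.time()[3]
      pp <- preprocess_volume(red); tm["pre"] <- proc.time()[3] - t0
      t0 <- proc.time()[3]
      regions <- detect_volume(red, detector, preproc = pp)
      tm["detect"] <- proc.time()[3] - t0
      t0 <- proc.time()[3]
      merged <- merge_regions(regions); tm["merge"] <- proc.time()[3] - t0
      objects <- merged$objects
      assigned <- NULL; feats <- NULL
      if (!is.null(recognizer) && nrow(objects) > 0) {
        t0 <- proc.time()[3]
        feats <- featurize_volume(objects, pp$frame, q = q, K = K,
                                  z_scale = z_scale, depth = dim(red)[3],
                                  source_mode = source_mode,
                                  regions = merged$regions)
        tm["feat"] <- proc.time()[3] - t0
        t0 <- proc.time()[3]
        assigned <- assign_ids_within(recognizer, feats)
        tm["id"] <- proc.time()[3] - t0
        objects <- left_join(objects,
                             select(assigned, object_id, assigned_id,
                                    distance),
                             by = "object_id")
      }
      traces <- NULL
      if (!is.null(green)) {
        t0 <- proc.time()[3]
        traces <- extract_activity(merged$regions, red, green,
                                   map = channel_map)
        if (!is.null(assigned))
          traces <- left_join(traces,
                              select(assigned, object_id, assigned_id),
                              by = "object_id")
        tm["act"] <- proc.time()[3] - t0
      }
      list(objects = mutate(objects, volume = v, .before = 1),
           regions = mutate(merged$regions, volume = v, .before = 1),
           traces = if (!is.null(traces))
             mutate(traces, volume = v, .before = 1),
           timing = tm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- list(volume = v,
                                            message = conditionMessage(res))
    } else {
      all_objects[[v]] <- res$objects
      all_regions[[v]] <- res$regions
      if (!is.null(res$traces)) all_traces[[length(all_traces) + 1L]] <-
          res$traces
      timing[[v]] <- res$timing
    }
  }
  structure(list(objects = bind_rows(all_objects),
                 regions = bind_rows(all_regions),
                 traces = if (length(all_traces) > 0) bind_rows(all_traces),
                 timing = if (length(timing) > 0)
                   as_tibble(do.call(rbind, timing)),
                 errors = errors, config_hash = cfg_hash),
            class = "wt_pipeline_result")
}
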