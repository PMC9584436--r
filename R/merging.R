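#' Intersection over union of two boxes
#'
#' Boxes follow the half-open convention `[x, x+w) x [y, y+h)`; IoU is the
#' intersection area divided by the union area. Vectorised over the first
#' box set.
#'
#' @param x1,y1,w1,h1 first box(es).
#' @param x2,y2,w2,h2 second box.
#' @return IoU value(s) in `[0, 1]`.
#' @export
iou_box <- function(x1, y1, w1, h1, x2, y2, w2, h2) {
  iw <- pmax(0, pmin(x1 + w1, x2 + w2) - pmax(x1, x2))
  ih <- pmax(0, pmin(y1 + h1, y2 + h2) - pmax(y1, y2))
  inter <- iw * ih
  inter / (w1 * h1 + w2 * h2 - inter)
}

#' Pairwise IoU matrix between two region sets
#'
#' @param a,b data frames with `x`, `y`, `w`, `h` columns.
#' @return `nrow(a) x nrow(b)` matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(0, nrow(a), nrow(b)))
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(nrow(b)))
    out[, j] <- iou_box(a$x, a$y, a$w, a$h, b$x[j], b$y[j], b$w[j], b$h[j])
  out
}

# Maximum-total-weight one-to-one assignment on a (rectangular) non-negative
# weight matrix; zero-weight assignments are discarded. Returns a 2-column
# matrix of (row, col) pairs. Solved as a linear sum assignment problem after
# square zero-padding.
max_weight_assignment <- function(wm) {
  nr <- nrow(wm); nc <- ncol(wm)
  if (nr == 0 || nc == 0) return(matrix(integer(), ncol = 2))
  n <- max(nr, nc)
  sq <- matrix(0, n, n)
  sq[seq_len(nr), seq_len(nc)] <- wm
  sol <- clue::solve_LSAP(max(sq) - sq + 1)  # minimise cost = maximise weight
  rows <- seq_len(n); cols <- as.integer(sol)
  keep <- rows <= nr & cols <= nc
  rows <- rows[keep]; cols <- cols[keep]
  pos <- wm[cbind(rows, cols)] > 0
  cbind(row = rows[pos], col = cols[pos])
}

#' Match regions between two adjacent frames
#'
#' Edge weights are pairwise IoU values; weights below `tau` are set to zero,
#' and the Hungarian method finds the one-to-one assignment maximising total
#' weight. Zero-weight assignments are discarded from the edge set.
#'
#' @param regions_z,regions_z1 region tibbles (`x, y, w, h` columns) for
#'   frames z and z + 1.
#' @param tau IoU threshold below which overlaps are ignored (default 0.05).
#' @return A tibble `from, to, weight` (row indices into the two inputs).
#' @export
match_adjacent <- function(regions_z, regions_z1, tau = 0.05) {
  wm <- iou_matrix(regions_z, regions_z1)
  wm[wm < tau] <- 0
  edges <- max_weight_assignment(wm)
  if (nrow(edges) == 0)
    return(tibble(from = integer(), to = integer(), weight = numeric()))
  tibble(from = as.integer(edges[, 1]), to = as.integer(edges[, 2]),
         weight = wm[edges])
}

#' Link per-frame regions into 3D neuron objects
#'
#' The chain of bipartite matching problems between adjacent frames is solved
#' independently per pair (the total weight is separable across pairs);
#' selected edges are chased into chains, each chain becoming one neuron
#' object; any unmatched region starts its own single-frame object. The
#' output satisfies the exclusion principle (at most one region per frame per
#' object) and the continuum principle (each object occupies consecutive
#' frames).
#'
#' @param regions a region tibble with at least `x, y, w, h, z`; `z` is the
#'   1-based frame index.
#' @param tau IoU threshold passed to [match_adjacent()].
#' @return The input tibble with an added integer `object_id` column.
#' @export
link_volume <- function(regions, tau = 0.05) {
  n <- nrow(regions)
  if (n == 0) return(mutate(regions, object_id = integer()))
  idx_by_z <- split(seq_len(n), regions$z)
  zs <- sort(unique(regions$z))
  succ <- rep(NA_integer_, n)
  for (k in seq_len(length(zs) - 1)) {
    if (zs[k + 1] != zs[k] + 1) next     # gap: continuum forbids linking
    i0 <- idx_by_z[[as.character(zs[k])]]
    i1 <- idx_by_z[[as.character(zs[k + 1])]]
    ed <- match_adjacent(regions[i0, ], regions[i1, ], tau)
    if (nrow(ed) > 0) succ[i0[ed$from]] <- i1[ed$to]
  }
  object_id <- rep(NA_integer_, n)
  next_id <- 0L
  ord <- order(regions$z, regions$x, regions$y)
  for (i in ord) {
    if (!is.na(object_id[i])) next
    next_id <- next_id + 1L
    j <- i
    while (!is.na(j) && is.na(object_id[j])) {
      object_id[j] <- next_id
      j <- succ[j]
    }
  }
  mutate(regions, object_id = object_id)
}

# 3-point moving average with endpoint replication.
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  xp <- c(x[1], x, x[n])
  (xp[1:n] + xp[2:(n + 1)] + xp[3:(n + 2)]) / 3
}

# Strict interior local minima of a profile (plateaus are not minima).
interior_minima <- function(p) {
  n <- length(p)
  if (n < 3) return(integer())
  which(p[2:(n - 1)] < p[1:(n - 2)] & p[2:(n - 1)] < p[3:n]) + 1L
}

#' Split accidentally fused neuron objects
#'
#' If the mean-intensity profile I(z) of an object has a strict interior
#' local minimum at z0, the object is split there: neighbouring neurons fused
#' along Z produce a dip in intensity between their two peaks. The region at
#' z0 joins the later (higher-z) part, which keeps both parts non-empty even
#' when the minimum sits at the second frame. Applied recursively, so
#' multiple minima yield multiple objects; outputs retain consecutive frames.
#'
#' @param profile numeric vector of per-frame mean intensities, ordered by z.
#' @param smooth smooth the profile with a 3-point mean before the scan?
#' @return An integer vector the same length as `profile`, numbering the
#'   output parts 1, 2, ... in z order.
#' @export
split_profile <- function(profile, smooth = FALSE) {
  p <- if (smooth) smooth3(profile) else profile
  cuts <- interior_minima(p)
  part <- rep(1L, length(profile))
  for (z0 in cuts) part[z0:length(profile)] <- part[z0] + 1L
  cumsum(c(1L, diff(part) != 0))  # renumber consecutively
}

#' Merge per-frame regions of one volume into 3D neuron objects
#'
#' Runs [link_volume()] then the fused-object split rule on every linked
#' chain, and summarises objects. Mean region intensity must be present
#' (column `mean_intensity`) for the split step; without it no splitting is
#' attempted.
#'
#' @inheritParams link_volume
#' @param smooth passed to [split_profile()].
#' @param max_len optional upper bound on object length in frames; over-long
#'   objects are re-split at their weakest internal IoU link.
#' @return A list: `regions` (input plus `object_id`) and `objects` (tibble
#'   `object_id, n_regions, z_start, z_end, cx, cy, cz, mean_intensity`).
#' @export
merge_regions <- function(regions, tau = 0.05, smooth = FALSE,
                          max_len = NULL) {
  linked <- link_volume(regions, tau)
  if (nrow(linked) == 0)
    return(list(regions = linked,
                objects = tibble(object_id = integer(), n_regions = integer(),
                                 z_start = integer(), z_end = integer(),
                                 cx = numeric(), cy = numeric(),
                                 cz = numeric(), mean_intensity = numeric())))
  has_int <- "mean_intensity" %in% names(linked)
  new_id <- linked$object_id
  nxt <- 0L
  for (oid in sort(unique(linked$object_id))) {
    rows <- which(linked$object_id == oid)
    rows <- rows[order(linked$z[rows])]
    part <- if (has_int && length(rows) >= 3)
      split_profile(linked$mean_intensity[rows], smooth) else
        rep(1L, length(rows))
    if (!is.null(max_len)) part <- enforce_max_len(linked[rows, ], part, max_len)
    for (p in unique(part)) {
      nxt <- nxt + 1L
      new_id[rows[part == p]] <- nxt
    }
  }
  linked$object_id <- new_id
  objects <- linked |>
    mutate(.cx = x + w / 2, .cy = y + h / 2) |>
    group_by(object_id) |>
    summarise(n_regions = n(), z_start = min(z), z_end = max(z),
              cx = mean(.cx), cy = mean(.cy), cz = mean(z),
              mean_intensity = if (has_int) mean(mean_intensity) else NA_real_,
              .groups = "drop") |>
    arrange(z_start, cx, cy)
  # renumber objects deterministically by (z_start, cx, cy)
  remap <- setNames(seq_len(nrow(objects)), objects$object_id)
  objects$object_id <- as.integer(remap[as.character(objects$object_id)])
  linked$object_id <- as.integer(remap[as.character(linked$object_id)])
  list(regions = linked, objects = arrange(objects, object_id))
}

# Re-split parts longer than max_len frames at their weakest IoU link.
enforce_max_len <- function(rows_tbl, part, max_len) {
  repeat {
    lens <- table(part)
    long <- names(lens)[lens > max_len]
    if (length(long) == 0) return(cumsum(c(1L, diff(part) != 0)))
    p <- as.integer(long[1])
    idx <- which(part == p)
    w <- vapply(seq_len(length(idx) - 1), function(k)
      iou_box(rows_tbl$x[idx[k]], rows_tbl$y[idx[k]],
              rows_tbl$w[idx[k]], rows_tbl$h[idx[k]],
              rows_tbl$x[idx[k + 1]], rows_tbl$y[idx[k + 1]],
              rows_tbl$w[idx[k + 1]], rows_tbl$h[idx[k + 1]]), numeric(1))
    cut <- which.min(w)
    part[idx[(cut + 1):length(idx)]] <- max(part) + 1L
  }
}

#' Evaluate 3D merging against ground truth
#'
#' A predicted object is a true positive if it can be matched one-to-one to a
#' ground-truth object such that member regions on shared frames overlap with
#' mean IoU >= `iou_threshold` and the two frame spans agree on at least half
#' of their union. Matching is greedy by descending mean IoU.
#'
#' @param pred_regions region tibble with `object_id` (from [merge_regions()]).
#' @param gt_regions ground-truth region tibble with `id` (neuron identity).
#' @param iou_threshold mean-IoU threshold for a valid match.
#' @return A tibble `precision, recall, f1, tp, n_pred, n_gt`.
#' @export
evaluate_merging <- function(pred_regions, gt_regions, iou_threshold = 0.3) {
  stopif_not(nrow(gt_regions) > 0, "empty ground truth")
  pids <- sort(unique(pred_regions$object_id))
  gids <- sort(unique(gt_regions$id))
  cand <- list()
  for (i in seq_along(pids)) {
    p <- pred_regions[pred_regions$object_id == pids[i], ]
    for (j in seq_along(gids)) {
      g <- gt_regions[gt_regions$id == gids[j], ]
      shared <- intersect(p$z, g$z)
      if (length(shared) == 0) next
      span_u <- length(union(p$z, g$z))
      if (length(shared) < span_u / 2) next
      ious <- vapply(shared, function(zz) {
        pr <- p[p$z == zz, ][1, ]; gr <- g[g$z == zz, ][1, ]
        iou_box(pr$x, pr$y, pr$w, pr$h, gr$x, gr$y, gr$w, gr$h)
      }, numeric(1))
      if (mean(ious) >= iou_threshold)
        cand[[length(cand) + 1L]] <- c(i = i, j = j, w = mean(ious))
    }
  }
  tp <- 0L
  if (length(cand) > 0) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, "w"]), , drop = FALSE]
    used_i <- logical(length(pids)); used_j <- logical(length(gids))
    for (k in seq_len(nrow(cm))) {
      i <- cm[k, "i"]; j <- cm[k, "j"]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE; tp <- tp + 1L
    }
  }
  precision <- if (length(pids) > 0) tp / length(pids) else NA_real_
  recall <- tp / length(gids)
  f1 <- if (!is.na(precision) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  tibble(precision = precision, recall = recall, f1 = f1,
         tp = tp, n_pred = length(pids), n_gt = length(gids))
}
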