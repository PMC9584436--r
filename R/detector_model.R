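# Detector network: each of the 5 concentric fields is bilinearly pooled to
# pool x pool pixels and flattened; a fully connected trunk with two residual
# blocks feeds a sigmoid score head and a 4-vector correction head whose
# scale ratios pass through exp() to guarantee positivity.

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

# Pooled multi-field features for a set of anchors on one frame.
# Fields are cropped at native size (anchor, 15, 31, 41, 81) and each resized
# to pool x pool; values are scaled to [0, 1] by the frame maximum.
detector_features <- function(frame, anchors, field_sizes = c(15, 31, 41, 81),
                              pool = 13L) {
  mx <- max(frame)
  f01 <- if (mx > 0) frame / mx else frame
  n <- nrow(anchors)
  sizes_all <- sort(unique(c(anchors$w, field_sizes)))
  Ms <- lapply(setNames(sizes_all, sizes_all),
               function(s) interp_matrix(as.integer(s), pool))
  out <- matrix(0, n, 5L * pool * pool)
  cx <- as.integer(round(anchors$x + (anchors$w - 1) / 2))
  cy <- as.integer(round(anchors$y + (anchors$h - 1) / 2))
  for (i in seq_len(n)) {
    sizes <- c(anchors$w[i], field_sizes)
    for (k in seq_along(sizes)) {
      s <- as.integer(sizes[k])
      crop <- crop_centered(f01, cx[i], cy[i], (s - 1L) %/% 2L)
      M <- Ms[[as.character(s)]]
      out[i, ((k - 1L) * pool * pool + 1L):(k * pool * pool)] <-
        M %*% crop %*% t(M)
    }
  }
  out
}

init_mat <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

detector_init <- function(n_in, hidden = 256L) {
  list(W1 = init_mat(n_in, hidden), b1 = rep(0, hidden),
       Wa1 = init_mat(hidden, hidden), ba1 = rep(0, hidden),
       Wa2 = init_mat(hidden, hidden) * 0.1, ba2 = rep(0, hidden),
       Wb1 = init_mat(hidden, hidden), bb1 = rep(0, hidden),
       Wb2 = init_mat(hidden, hidden) * 0.1, bb2 = rep(0, hidden),
       Ws = init_mat(hidden, 1L) * 0.1, bs = 0,
       Wc = init_mat(hidden, 4L) * 0.1, bc = rep(0, 4))
}

addb <- function(m, b) sweep(m, 2, b, "+")

detector_forward <- function(p, X) {
  S1 <- addb(X %*% p$W1, p$b1);  H1 <- relu(S1)
  Sa <- addb(H1 %*% p$Wa1, p$ba1); A1 <- relu(Sa)
  S2 <- H1 + addb(A1 %*% p$Wa2, p$ba2); H2 <- relu(S2)
  Sb <- addb(H2 %*% p$Wb1, p$bb1); B1 <- relu(Sb)
  S3 <- H2 + addb(B1 %*% p$Wb2, p$bb2); H3 <- relu(S3)
  u <- addb(H3 %*% p$Ws, p$bs)
  cr <- addb(H3 %*% p$Wc, p$bc)
  list(S1 = S1, H1 = H1, Sa = Sa, A1 = A1, S2 = S2, H2 = H2,
       Sb = Sb, B1 = B1, S3 = S3, H3 = H3, u = u, cr = cr,
       score = sigmoid(u[, 1]),
       dx = cr[, 1], dy = cr[, 2], omega = exp(cr[, 3]), eta = exp(cr[, 4]))
}

# Joint loss: binary cross-entropy on the score over all anchors plus L2 on
# (dx, dy, omega, eta) over positive anchors. Returns loss and gradients.
detector_backward <- function(p, X, fw, y, targets, lambda = 1) {
  n <- nrow(X)
  s <- clamp(fw$score, 1e-7, 1 - 1e-7)
  bce <- -mean(y * log(s) + (1 - y) * log(1 - s))
  du <- matrix((s - y) / n, ncol = 1)

  pos <- which(!is.na(targets[, 1]))
  npos <- max(1L, length(pos))
  dcr <- matrix(0, n, 4)
  l2 <- 0
  if (length(pos) > 0) {
    dpred <- cbind(fw$dx[pos], fw$dy[pos], fw$omega[pos], fw$eta[pos]) -
      targets[pos, , drop = FALSE]
    l2 <- sum(dpred^2) / npos
    g <- 2 * lambda * dpred / npos
    g[, 3] <- g[, 3] * fw$omega[pos]    # through exp()
    g[, 4] <- g[, 4] * fw$eta[pos]
    dcr[pos, ] <- g
  }

  dH3 <- du %*% t(p$Ws) + dcr %*% t(p$Wc)
  dS3 <- dH3 * (fw$S3 > 0)
  dB1 <- dS3 %*% t(p$Wb2)
  dSb <- dB1 * (fw$Sb > 0)
  dH2 <- dS3 + dSb %*% t(p$Wb1)
  dS2 <- dH2 * (fw$S2 > 0)
  dA1 <- dS2 %*% t(p$Wa2)
  dSa <- dA1 * (fw$Sa > 0)
  dH1 <- dS2 + dSa %*% t(p$Wa1)
  dS1 <- dH1 * (fw$S1 > 0)

  grads <- list(W1 = t(X) %*% dS1, b1 = colSums(dS1),
                Wa1 = t(fw$H1) %*% dSa, ba1 = colSums(dSa),
                Wa2 = t(fw$A1) %*% dS2, ba2 = colSums(dS2),
                Wb1 = t(fw$H2) %*% dSb, bb1 = colSums(dSb),
                Wb2 = t(fw$B1) %*% dS3, bb2 = colSums(dS3),
                Ws = t(fw$H3) %*% du, bs = sum(du),
                Wc = t(fw$H3) %*% dcr, bc = colSums(dcr))
  list(loss = bce + lambda * l2, bce = bce, l2 = l2, grads = grads)
}

# Cosine-annealed learning rate with warm restarts.
sgdr_lr <- function(step, steps_per_cycle, lr_max, lr_min = 1e-4, mult = 2) {
  t <- step; cycle_len <- steps_per_cycle
  while (t >= cycle_len) { t <- t - cycle_len; cycle_len <- cycle_len * mult }
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * t / cycle_len))
}

sgd_step <- function(params, vel, grads, lr, momentum = 0.9, clip = 5) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > clip)
    grads <- lapply(grads, function(g) g * clip / gn)
  for (nm in names(grads)) {
    vel[[nm]] <- momentum * vel[[nm]] - lr * grads[[nm]]
    params[[nm]] <- params[[nm]] + vel[[nm]]
  }
  list(params = params, vel = vel)
}

# Collect training anchors (features, score labels, correction targets) from
# annotated volumes. Positive if max-IoU ground truth >= pos_iou; negative if
# < neg_iou; in-between ignored.
collect_training_anchors <- function(volumes, annotations, anchor_sizes,
                                     pos_iou, neg_iou, pool,
                                     preprocs = NULL) {
  feats <- list(); ys <- list(); tg <- list()
  for (v in seq_along(volumes)) {
    vol <- volumes[[v]]
    gt_v <- filter(annotations, volume == v)
    if (nrow(gt_v) == 0) next
    pp <- if (!is.null(preprocs)) preprocs[[v]] else preprocess_volume(vol)
    for (zf in seq_len(dim(vol)[3])) {
      fr <- vol[, , zf]
      peaks <- find_local_maxima(fr, mask = pp$head$head_mask)
      if (nrow(peaks) == 0) next
      anchors <- make_anchors(peaks, anchor_sizes,
                              img_size = c(ncol(fr), nrow(fr)), z = zf)
      gt_z <- filter(gt_v, z == zf)
      wm <- iou_matrix(anchors, gt_z)
      best <- if (ncol(wm) > 0) apply(wm, 1, max) else rep(0, nrow(anchors))
      lab <- ifelse(best >= pos_iou, 1L, ifelse(best < neg_iou, 0L, NA))
      keep <- which(!is.na(lab))
      if (length(keep) == 0) next
      anchors <- anchors[keep, ]; lab <- lab[keep]; wm <- wm[keep, , drop = FALSE]
      tmat <- matrix(NA_real_, length(keep), 4)
      posi <- which(lab == 1L)
      if (length(posi) > 0) {
        gidx <- apply(wm[posi, , drop = FALSE], 1, which.max)
        tmat[posi, ] <- as.matrix(correction_targets(anchors[posi, ],
                                                     gt_z[gidx, ]))
      }
      feats[[length(feats) + 1L]] <- detector_features(fr, anchors, pool = pool)
      ys[[length(ys) + 1L]] <- lab
      tg[[length(tg) + 1L]] <- tmat
    }
  }
  list(X = do.call(rbind, feats), y = unlist(ys), targets = do.call(rbind, tg))
}

#' Train the anchor-box region detector
#'
#' Builds multi-field training patches from annotated volumes (anchors on
#' local maxima inside the segmented head; positives are anchors whose
#' best-overlap ground truth reaches `pos_iou`), then minimises binary
#' cross-entropy on the region score plus L2 on the bounding-box corrections
#' of positive anchors, by momentum SGD with cosine-annealed warm restarts.
#' Fully reproducible given `seed`.
#'
#' @param volumes list of `H x W x Z` arrays.
#' @param annotations tibble of ground-truth regions with columns
#'   `volume, x, y, w, h, z`.
#' @param anchor_sizes anchor side length(s); default the single 9 x 9 box.
#' @param pos_iou,neg_iou anchor assignment thresholds (default 0.3 / 0.1;
#'   anchors in between are ignored).
#' @param neg_ratio maximum negatives kept per positive (subsampled, seeded).
#' @param pool per-field pooled side length of the network input.
#' @param hidden trunk width.
#' @param epochs,batch,lr_max,restart_epochs SGDR settings.
#' @param max_train cap on the number of training patches (balanced subsample).
#' @param preprocs optional list of precomputed [preprocess_volume()] results
#'   (one per volume), to avoid recomputing head segmentations.
#' @param lambda weight of the correction L2 term.
#' @param seed integer seed for all training randomness.
#' @return An object of class `wt_detector`.
#' @export
train_detector <- function(volumes, annotations, anchor_sizes = 9L,
                           pos_iou = 0.3, neg_iou = 0.1, neg_ratio = 2,
                           pool = 13L, hidden = 256L, epochs = 20L,
                           batch = 256L, lr_max = 0.01, restart_epochs = 10L,
                           lambda = 1, max_train = 9000L, seed = 0L,
                           preprocs = NULL) {
  stopif_not(length(volumes) >= 1, "need at least one annotated volume")
  dat <- collect_training_anchors(volumes, annotations, anchor_sizes,
                                  pos_iou, neg_iou, pool, preprocs)
  if (is.null(dat$X) || sum(dat$y == 1L) == 0)
    abort("no positive anchors found in the training volumes")
  with_seed(child_seed(seed, 0L, 11L), {
    posi <- which(dat$y == 1L); negi <- which(dat$y == 0L)
    if (length(negi) > neg_ratio * length(posi))
      negi <- sort(sample(negi, neg_ratio * length(posi)))
    sel <- sort(c(posi, negi))
    if (length(sel) > max_train) sel <- sort(sample(sel, max_train))
    X <- dat$X[sel, , drop = FALSE]
    y <- dat$y[sel]; targets <- dat$targets[sel, , drop = FALSE]

    mu <- colMeans(X)
    sdv <- pmax(apply(X, 2, sd), 1e-6)
    X <- sweep(sweep(X, 2, mu), 2, sdv, "/")

    params <- detector_init(ncol(X), hidden)
    vel <- lapply(params, function(p) p * 0)
    n <- nrow(X)
    steps_per_epoch <- ceiling(n / batch)
    history <- tibble(epoch = integer(), loss = numeric(), bce = numeric(),
                      l2 = numeric(), lr = numeric())
    step <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- ep_bce <- ep_l2 <- 0
      for (b in seq_len(steps_per_epoch)) {
        rows <- ord[((b - 1) * batch + 1):min(b * batch, n)]
        Xb <- X[rows, , drop = FALSE]
        fw <- detector_forward(params, Xb)
        bw <- detector_backward(params, Xb, fw, y[rows],
                                targets[rows, , drop = FALSE], lambda)
        lr <- sgdr_lr(step, restart_epochs * steps_per_epoch, lr_max)
        upd <- sgd_step(params, vel, bw$grads, lr)
        params <- upd$params; vel <- upd$vel
        step <- step + 1
        ep_loss <- ep_loss + bw$loss * length(rows)
        ep_bce <- ep_bce + bw$bce * length(rows)
        ep_l2 <- ep_l2 + bw$l2 * length(rows)
      }
      history <- bind_rows(history, tibble(
        epoch = ep, loss = ep_loss / n, bce = ep_bce / n, l2 = ep_l2 / n,
        lr = sgdr_lr(step - 1, restart_epochs * steps_per_epoch, lr_max)))
    }
    structure(list(params = params, mu = mu, sd = sdv,
                   anchor_sizes = anchor_sizes, pool = pool,
                   hidden = hidden, pos_iou = pos_iou, neg_iou = neg_iou,
                   n_train = n, n_pos = length(posi), history = history,
                   seed = seed),
              class = "wt_detector")
  })
}

#' Detect neuronal regions in one volume
#'
#' Segments the head, finds local maxima per frame, scores and corrects
#' anchor boxes with the trained network, and applies per-frame non-maximum
#' suppression. Inference is deterministic.
#'
#' @param volume `H x W x Z` array.
#' @param model a `wt_detector`.
#' @param preproc optional result of [preprocess_volume()] (recomputed if
#'   missing).
#' @param score_floor,overlap_threshold NMS settings (defaults 0.4 / 0.20).
#' @return A region tibble `x, y, w, h, z, score, mean_intensity` with
#'   integer pixel boxes (`w, h >= 1`).
#' @export
detect_volume <- function(volume, model, preproc = NULL,
                          score_floor = 0.4, overlap_threshold = 0.20) {
  preproc <- preproc %||% preprocess_volume(volume)
  out <- list()
  for (zf in seq_len(dim(volume)[3])) {
    fr <- volume[, , zf]
    peaks <- find_local_maxima(fr, mask = preproc$head$head_mask)
    if (nrow(peaks) == 0) next
    anchors <- make_anchors(peaks, model$anchor_sizes,
                            img_size = c(ncol(fr), nrow(fr)), z = zf)
    X <- detector_features(fr, anchors, pool = model$pool)
    X <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
    fw <- detector_forward(model$params, X)
    reg <- apply_correction(anchors,
                            tibble(dx = fw$dx, dy = fw$dy,
                                   omega = fw$omega, eta = fw$eta))
    reg$score <- fw$score
    out[[length(out) + 1L]] <- reg
  }
  if (length(out) == 0) return(empty_regions())
  regions <- nms(bind_rows(out), score_floor, overlap_threshold)
  if (nrow(regions) == 0) return(empty_regions())
  regions <- mutate(regions,
                    x = round(x), y = round(y),
                    w = pmax(1, round(w)), h = pmax(1, round(h)))
  regions$mean_intensity <- vapply(seq_len(nrow(regions)), function(i)
    box_mean_intensity(volume[, , regions$z[i]], regions$x[i], regions$y[i],
                       regions$w[i], regions$h[i]), numeric(1))
  arrange(regions, z, x, y)
}
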