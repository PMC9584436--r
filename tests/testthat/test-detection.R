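test_that("local maxima are found above the floor, deterministically ordered", {
  img <- matrix(0, 20, 20)
  img[5, 5] <- 10; img[15, 12] <- 8
  pk <- find_local_maxima(img, floor = 1)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$px, c(4L, 11L))   # row-major: y=4 first, then y=14
  expect_equal(pk$py, c(4L, 14L))

  expect_equal(nrow(find_local_maxima(matrix(3, 10, 10))), 0L)

  ds <- tiny_ds()
  v <- ds$volumes[[1]]
  pp <- preprocess_volume(v$red)
  hits <- 0; tot <- 0
  for (zf in seq_len(dim(v$red)[3])) {
    g <- v$gt$regions[v$gt$regions$z == zf, ]
    if (nrow(g) == 0) next
    pk <- find_local_maxima(v$red[, , zf], mask = pp$head$head_mask)
    for (i in seq_len(nrow(g))) {
      cx <- g$x[i] + g$w[i] / 2; cy <- g$y[i] + g$h[i] / 2
      tot <- tot + 1
      if (nrow(pk) > 0 && min((pk$px - cx)^2 + (pk$py - cy)^2) <= 9)
        hits <- hits + 1
    }
  }
  expect_gte(hits / tot, 0.9)
})

test_that("anchors are centred on peaks, one per (peak, size) pair", {
  pk <- tibble::tibble(px = 10L, py = 10L, value = 1)
  a9 <- make_anchors(pk, 9L)
  expect_equal(c(a9$x, a9$y, a9$w, a9$h), c(6, 6, 9, 9))

  pk3 <- tibble::tibble(px = c(5L, 9L, 30L), py = c(5L, 22L, 7L), value = 1)
  expect_equal(nrow(make_anchors(pk3, c(7L, 11L))), 6L)

  corner <- make_anchors(tibble::tibble(px = 0L, py = 0L, value = 1), 9L,
                         img_size = c(64, 64))
  expect_true(corner$clipped)
  expect_equal(nrow(corner), 1L)
})

test_that("multi-field crops are concentric, scaled and zero-padded", {
  fr <- matrix(runif(80 * 80, 0, 200), 80, 80)
  fr[41, 41] <- 250  # centre value (x = 40, y = 40)
  anchor <- tibble::tibble(x = 36, y = 36, w = 9, h = 9, z = 1L)
  patch <- crop_multifield(fr, anchor)
  expect_equal(dim(patch), c(41, 41, 5))
  for (k in 1:4) expect_equal(patch[21, 21, k], 250 / max(fr))
  expect_true(all(patch >= 0 & patch <= 1))

  zero <- crop_multifield(matrix(0, 60, 60),
                          tibble::tibble(x = 26, y = 26, w = 9, h = 9))
  expect_true(all(zero == 0))

  # anchor at the image corner: out-of-image area is zero in all channels
  edge <- crop_multifield(matrix(1, 60, 60),
                          tibble::tibble(x = -4, y = -4, w = 9, h = 9))
  expect_equal(edge[6, 6, 3], 0)           # 31-field pixel outside the image
  expect_gt(edge[21, 21, 3], 0)            # centre is inside
})

test_that("correction targets and application invert each other exactly", {
  anchor <- tibble::tibble(x = 10, y = 10, w = 9, h = 9, z = 1L)
  expect_equal(as.numeric(correction_targets(anchor, anchor)), c(0, 0, 1, 1))

  gt <- tibble::tibble(x = 12, y = 11, w = 7, h = 10)
  expect_equal(as.numeric(correction_targets(anchor, gt)),
               c(2 / 9, 1 / 9, 7 / 9, 10 / 9))

  a2 <- tibble::tibble(x = 0, y = 0, w = 10, h = 10, z = 1L)
  reg <- apply_correction(a2, tibble::tibble(dx = 0.5, dy = 0.5,
                                             omega = 0.5, eta = 0.5))
  expect_equal(as.numeric(reg[, c("x", "y", "w", "h")]), c(5, 5, 5, 5))

  reg0 <- apply_correction(anchor, tibble::tibble(dx = 0, dy = 0,
                                                  omega = 1, eta = 1))
  expect_equal(as.numeric(reg0[, c("x", "y", "w", "h")]),
               as.numeric(anchor[, c("x", "y", "w", "h")]))
})

test_that("non-maximum suppression keeps high scores and breaks overlap chains", {
  one <- tibble::tibble(x = 0, y = 0, w = 9, h = 9, z = 1L, score = 0.9)
  expect_equal(nrow(nms(one)), 1L)

  dup <- dplyr::bind_rows(one, dplyr::mutate(one, score = 0.8))
  kept <- nms(dup)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$score, 0.9)

  # A overlaps B, B overlaps C, A and C disjoint -> keep {A, C}
  abc <- tibble::tibble(x = c(0, 5, 10), y = 0, w = 10, h = 10, z = 1L,
                        score = c(0.9, 0.8, 0.7))
  kept2 <- nms(abc)
  expect_equal(sort(kept2$x), c(0, 10))

  # scores below the floor are dropped entirely
  low <- dplyr::mutate(one, score = 0.3)
  expect_equal(nrow(nms(low)), 0L)

  # output is overlap-free at the threshold and a subset of the input
  set.seed(9)
  rnd <- tibble::tibble(x = runif(40, 0, 60), y = runif(40, 0, 60),
                        w = 9, h = 9, z = 1L, score = runif(40, 0.4, 1))
  kr <- nms(rnd)
  expect_true(all(kr$score %in% rnd$score))
  if (nrow(kr) > 1) {
    im <- iou_matrix(kr, kr); diag(im) <- 0
    expect_lte(max(im), 0.20)
  }
})

test_that("detection metrics follow the greedy one-to-one matching definition", {
  gt <- tibble::tibble(x = c(0, 20), y = c(0, 20), w = 9, h = 9, z = 1L)
  ev <- evaluate_detection(gt, gt)
  expect_equal(c(ev$precision, ev$recall, ev$f1), c(1, 1, 1))

  far <- dplyr::mutate(gt, x = x + 100)
  ev0 <- evaluate_detection(far, gt)
  expect_equal(c(ev0$precision, ev0$recall, ev0$f1), c(0, 0, 0))

  ev5 <- evaluate_detection(gt[1, ], gt)
  expect_equal(c(ev5$precision, ev5$recall, ev5$f1), c(1, 0.5, 2 / 3))

  expect_error(evaluate_detection(gt, gt[0, ]), "empty ground truth")
})

test_that("detector training is reproducible and its loss decreases", {
  ds <- tiny_ds()
  vols <- lapply(ds$volumes, function(v) v$red)
  ann <- dplyr::bind_rows(lapply(ds$volumes, function(v)
    dplyr::mutate(v$gt$regions, volume = v$volume_index)))
  d1 <- train_detector(vols, ann, epochs = 6L, seed = 3)
  d2 <- train_detector(vols, ann, epochs = 6L, seed = 3)
  expect_identical(d1$history, d2$history)
  expect_identical(d1$params$W1, d2$params$W1)
  expect_lt(tail(d1$history$loss, 1), d1$history$loss[1])

  pred <- detect_volume(ds$volumes[[1]]$red, d1)
  expect_true(all(pred$w >= 1 & pred$h >= 1))
  expect_true(all(pred$score >= 0.4))
})
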