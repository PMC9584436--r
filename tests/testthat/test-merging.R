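test_that("box IoU matches pixel-set counting and is symmetric", {
  expect_equal(iou_box(3, 4, 5, 6, 3, 4, 5, 6), 1)
  expect_equal(iou_box(0, 0, 4, 4, 10, 10, 4, 4), 0)
  expect_equal(iou_box(0, 0, 4, 4, 2, 2, 4, 4), 4 / 28)
  expect_equal(iou_box(0, 0, 4, 4, 2, 2, 4, 4),
               iou_box(2, 2, 4, 4, 0, 0, 4, 4))
})

test_that("adjacent-frame matching equals the exhaustive matching optimum", {
  expect_equal(nrow(match_adjacent(
    tibble::tibble(x = 1, y = 1, w = 5, h = 5),
    tibble::tibble(x = numeric(), y = numeric(), w = numeric(),
                   h = numeric()))), 0L)

  a <- tibble::tibble(x = 0, y = 0, w = 4, h = 4)
  b <- tibble::tibble(x = 2, y = 0, w = 4, h = 4)
  ed <- match_adjacent(a, b)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$weight, iou_box(0, 0, 4, 4, 2, 0, 4, 4))

  set.seed(0)
  for (rep in 1:30) {
    na <- sample(1:4, 1); nb <- sample(1:4, 1)
    ra <- tibble::tibble(x = runif(na, 0, 20), y = runif(na, 0, 20),
                         w = runif(na, 3, 8), h = runif(na, 3, 8))
    rb <- tibble::tibble(x = runif(nb, 0, 20), y = runif(nb, 0, 20),
                         w = runif(nb, 3, 8), h = runif(nb, 3, 8))
    wm <- iou_matrix(ra, rb); wm[wm < 0.05] <- 0
    ed <- match_adjacent(ra, rb)
    expect_equal(sum(ed$weight), brute_max_assignment_weight(wm),
                 tolerance = 1e-12)
  }
})

test_that("volume linking reproduces generator objects and partitions regions", {
  # well-separated blobs so each stack is unambiguous
  ds0 <- generate_dataset(1, layout_spec(n_neurons = 25, exclusion_radius = 14,
                                         interframe_shift_px = 0, seed = 11))
  v <- ds0$volumes[[1]]
  regs <- dplyr::mutate(v$gt$regions, mean_intensity = NA_real_)
  linked <- link_volume(regs)
  expect_equal(nrow(linked), nrow(regs))          # partition covers all
  expect_equal(length(unique(linked$object_id)), nrow(v$gt$objects))
  spans <- linked |> dplyr::group_by(object_id) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  expect_equal(sort(spans$n),
               sort(as.integer(table(v$gt$regions$id))))

  # mutually disjoint boxes across frames -> every region its own object
  disj <- tibble::tibble(x = c(0, 30, 60), y = c(0, 30, 60), w = 5, h = 5,
                         z = 1:3)
  expect_equal(link_volume(disj)$object_id, 1:3)
})

test_that("linking equals the exhaustive chain optimum on small instances", {
  set.seed(1)
  for (rep in 1:30) {
    regs <- dplyr::bind_rows(lapply(1:3, function(zf) {
      n <- sample(1:4, 1)
      tibble::tibble(x = runif(n, 0, 25), y = runif(n, 0, 25),
                     w = runif(n, 4, 9), h = runif(n, 4, 9), z = zf)
    }))
    linked <- link_volume(regs)
    # total linked weight
    tot <- 0
    for (zf in 1:2) {
      a <- linked[linked$z == zf, ]; b <- linked[linked$z == zf + 1, ]
      for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
        if (a$object_id[i] == b$object_id[j]) {
          w <- iou_box(a$x[i], a$y[i], a$w[i], a$h[i],
                       b$x[j], b$y[j], b$w[j], b$h[j])
          if (w >= 0.05) tot <- tot + w
        }
      }
    }
    # chain optimum decomposes into independent per-pair optima
    opt <- 0
    for (zf in 1:2) {
      wm <- iou_matrix(regs[regs$z == zf, ], regs[regs$z == zf + 1, ])
      wm[wm < 0.05] <- 0
      opt <- opt + brute_max_assignment_weight(wm)
    }
    expect_equal(tot, opt, tolerance = 1e-12)
  }
})

test_that("the split rule cuts at strict interior intensity minima only", {
  expect_equal(split_profile(c(3, 5, 8)), c(1L, 1L, 1L))
  expect_equal(split_profile(c(5, 9, 4, 8, 6)), c(1L, 1L, 2L, 2L, 2L))
  expect_equal(split_profile(7), 1L)
  expect_equal(split_profile(c(5, 5, 5)), c(1L, 1L, 1L))   # plateau: no cut
  expect_equal(split_profile(c(9, 4, 8, 3, 7)),
               c(1L, 2L, 2L, 3L, 3L))                      # two minima

  # through merge_regions: a fused two-peak object is cut in two
  regs <- tibble::tibble(x = 10, y = 10, w = 8, h = 8, z = 1:5,
                         mean_intensity = c(5, 9, 4, 8, 6))
  out <- merge_regions(regs)
  expect_equal(nrow(out$objects), 2L)
  expect_equal(out$objects$z_start, c(1, 3))
  expect_equal(sort(as.integer(table(out$regions$object_id))), c(2L, 3L))

  # split never merges and conserves the region multiset
  expect_equal(nrow(out$regions), nrow(regs))
})

test_that("merging evaluation matches hand counts on a toy volume", {
  gt <- tibble::tibble(id = rep(1:3, times = c(3, 2, 1)),
                       x = rep(c(0, 20, 40), times = c(3, 2, 1)),
                       y = rep(c(0, 20, 40), times = c(3, 2, 1)),
                       w = 8, h = 8, z = c(1, 2, 3, 1, 2, 1))
  pred <- dplyr::rename(gt, object_id = id)
  perfect <- evaluate_merging(pred, gt)
  expect_equal(perfect$f1, 1)

  # all singletons: precision/recall suffer on multi-frame objects
  singl <- dplyr::mutate(pred, object_id = dplyr::row_number())
  ev <- evaluate_merging(singl, gt)
  expect_lt(ev$recall, 1)

  # hand-built: objects 2 and 3 correct, object 1 split in two ->
  # TP = 2 (greedy matches the 2-frame piece of object 1 fails span rule)
  split1 <- dplyr::mutate(pred,
                          object_id = c(1L, 1L, 4L, 2L, 2L, 3L))
  ev2 <- evaluate_merging(split1, gt)
  expect_equal(ev2$tp, 3L)   # the 2/3-frame piece still passes span overlap
  expect_equal(ev2$n_pred, 4L)
  expect_equal(ev2$precision, 3 / 4)
  expect_equal(ev2$recall, 1)
})
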