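test_that("the margin loss reduces to scaled softmax cross-entropy", {
  set.seed(5)
  for (rep in 1:20) {
    d <- sample(4:16, 1); N <- sample(3:8, 1)
    cvec <- rnorm(d); W <- matrix(rnorm(d * N), d, N)
    xi <- sample(N, 1); s <- runif(1, 5, 40)
    expect_equal(margin_loss(cvec, xi, W, s = s, m1 = 1, m2 = 0, m3 = 0),
                 softmax_ce_oracle(cvec, xi, W, s), tolerance = 1e-8)
  }
})

test_that("the loss vanishes for a perfectly aligned embedding at large scale", {
  d <- 6; N <- 4
  W <- diag(1, d)[, 1:N]
  cvec <- W[, 2]
  # theta_xi = 0, other thetas = pi/2; margins shift cos by a fixed amount
  l <- margin_loss(cvec, 2L, W, s = 200, m1 = 1, m2 = 0, m3 = 0)
  expect_lt(l, 1e-8)
})

test_that("the loss is monotone in the additive margins", {
  set.seed(11)
  for (rep in 1:10) {
    d <- 8; N <- 5
    cvec <- rnorm(d); W <- matrix(rnorm(d * N), d, N); xi <- sample(N, 1)
    ms <- seq(0, 0.5, by = 0.05)
    l2 <- vapply(ms, function(m)
      margin_loss(cvec, xi, W, s = 20, m1 = 1.0, m2 = m, m3 = 0), numeric(1))
    l3 <- vapply(ms, function(m)
      margin_loss(cvec, xi, W, s = 20, m1 = 1.0, m2 = 0, m3 = m), numeric(1))
    expect_true(all(diff(l2) >= -1e-10))
    expect_true(all(diff(l3) >= -1e-10))
  }
})

test_that("Hungarian ID assignment equals the brute-force permutation optimum", {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(r) c(v[i], r)))
    out
  }
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    D <- matrix(runif(n * n, 0, 2), n, n)
    res <- wormtracker:::assign_by_distance(D, seq_len(n))
    got <- sum(D[cbind(res$row, res$assigned_id)])
    best <- min(vapply(perms(seq_len(n)), function(p)
      sum(D[cbind(seq_len(n), p)]), numeric(1)))
    expect_equal(got, best, tolerance = 1e-12)
  }

  # rectangular: extras are left unassigned at the padding cost
  D <- matrix(0.1, 3, 2)
  res <- wormtracker:::assign_by_distance(D, 1:2)
  expect_equal(sum(is.na(res$assigned_id)), 1L)
})

test_that("tracking accuracy counts per volume then averages", {
  a <- tibble::tibble(assigned_id = c(1L, 2L, 3L, 4L),
                      true_id = c(1L, 2L, 3L, 4L))
  expect_equal(evaluate_tracking(a), 1)
  expect_equal(evaluate_tracking(dplyr::mutate(a, assigned_id = NA)), 0)
  swap <- tibble::tibble(assigned_id = c(2L, 1L, 3L, 4L),
                         true_id = c(1L, 2L, 3L, 4L))
  expect_equal(evaluate_tracking(swap), 0.5)
  twovol <- dplyr::bind_rows(dplyr::mutate(a, volume = 1L),
                             dplyr::mutate(swap, volume = 2L))
  expect_equal(evaluate_tracking(twovol), 0.75)
  expect_error(evaluate_tracking(dplyr::mutate(a, true_id = NA)))
})

test_that("recognizer training is reproducible and separates the classes", {
  ds <- tiny_ds()
  feats <- gt_features(ds)
  tr <- dplyr::bind_rows(feats)
  m1 <- train_recognizer(tr, epochs = 60L, seed = 9)
  m2 <- train_recognizer(tr, epochs = 60L, seed = 9)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$Wcls, m2$params$Wcls)

  # class weight columns end up nearest their own class's embedding centroid
  Cn <- embed_features(m1, tr)
  cls <- match(tr$label, m1$class_ids)
  cents <- t(vapply(seq_along(m1$class_ids), function(k)
    colMeans(Cn[cls == k, , drop = FALSE]), numeric(m1$d)))
  cents <- cents / sqrt(rowSums(cents^2))
  Wn <- wormtracker:::normalize_cols(m1$params$Wcls)$M
  sim <- cents %*% Wn[, -m1$N, drop = FALSE]   # class x class cosine
  own_is_nearest <- vapply(seq_len(nrow(sim)), function(k)
    which.max(sim[k, ]) == k, logical(1))
  expect_gte(mean(own_is_nearest), 0.9)

  # within-volume assignment on training data is near-perfect
  a <- assign_ids_within(m1, feats[[1]])
  expect_gte(mean(a$assigned_id == feats[[1]]$label, na.rm = TRUE), 0.9)
})

test_that("across-animal mode uses the template as the class matrix", {
  ds <- tiny_ds()
  feats <- gt_features(ds)
  m <- train_recognizer(dplyr::bind_rows(feats), epochs = 60L, seed = 9)
  a_same <- assign_ids_across(m, feats[[2]], feats[[2]])
  expect_equal(a_same$assigned_id, feats[[2]]$label)   # identity mapping
  expect_equal(sum(a_same$distance), 0, tolerance = 1e-9)

  # permuting the test rows permutes the id map identically
  set.seed(2)
  p <- sample(nrow(feats[[3]]))
  a1 <- assign_ids_across(m, feats[[2]], feats[[3]])
  a2 <- assign_ids_across(m, feats[[2]], feats[[3]][p, ])
  expect_equal(a2$assigned_id, a1$assigned_id[p])
})
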