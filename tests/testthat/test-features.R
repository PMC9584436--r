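test_that("density feature bins points into the correct shell and territory", {
  fr <- identity_frame()
  dl <- 4; dz <- 2; q <- 3
  none <- density_feature(c(0, 0, 0),
                          tibble::tibble(x = numeric(), y = numeric(),
                                         z = numeric()),
                          fr, q = q, dl = dl, dz = dz)
  expect_true(all(none == 0))
  expect_length(none, q * 4)

  # one point at rho = 1.5*dl on the ventral axis (phi = 0), z = +0.5*dz:
  # exactly the (t = 2, z+, V) bin
  ctx <- tibble::tibble(x = 0, y = 1.5 * dl, z = 0.5 * dz)
  f <- density_feature(c(0, 0, 0), ctx, fr, q = q, dl = dl, dz = dz)
  expect_equal(sum(f), 1)
  expect_equal(unname(f[["t2_zplus_V"]]), 1)

  expect_error(density_feature(c(0, 0, 0), ctx, fr, q = 0, dl = dl, dz = dz))
  expect_error(density_feature(c(0, 0, 0), ctx, fr, q = 2, dl = -1, dz = dz))
})

test_that("density counts conserve and match the per-bin oracle", {
  fr <- identity_frame()
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    q <- sample(2:6, 1); dl <- runif(1, 2, 8); dz <- runif(1, 1, 4)
    ctx <- tibble::tibble(x = runif(n, -30, 30), y = runif(n, -30, 30),
                          z = runif(n, -8, 8))
    f <- density_feature(c(0, 0, 0), ctx, fr, q = q, dl = dl, dz = dz)
    rho <- sqrt(ctx$x^2 + ctx$y^2)
    in_outer <- rho <= q * dl & abs(ctx$z) <= q * dz / 2
    expect_equal(sum(f), sum(in_outer))
    oracle <- density_oracle(ctx$x, ctx$y, ctx$z, q, dl, dz)
    # oracle orders territories (z+V, z-V, z+D, z-D) within each t
    expect_equal(as.numeric(f), oracle)
  }
})

test_that("knn feature orders neighbours by distance with zero padding", {
  fr <- identity_frame()
  one <- knn_feature(c(0, 0, 0), tibble::tibble(x = 3, y = 4, z = 0), fr,
                     K = 1)
  expect_equal(unname(one[["rho1"]]), 5)

  two <- knn_feature(c(0, 0, 0),
                     tibble::tibble(x = c(2, 1), y = 0, z = 0), fr, K = 2)
  expect_equal(unname(two[["rho1"]]), 1)   # nearer first
  expect_equal(unname(two[["rho2"]]), 2)

  pad <- knn_feature(c(0, 0, 0), tibble::tibble(x = 1, y = 0, z = 0), fr,
                     K = 4)
  expect_length(pad, 12)
  expect_equal(attr(pad, "n_padded"), 3)
  expect_true(all(pad[4:12] == 0))

  expect_error(knn_feature(c(0, 0, 0),
                           tibble::tibble(x = numeric(), y = numeric(),
                                          z = numeric()), fr, K = 2))

  set.seed(3)
  for (rep in 1:20) {
    n <- sample(7:30, 1)
    ctx <- tibble::tibble(x = runif(n, -20, 20), y = runif(n, -20, 20),
                          z = runif(n, -5, 5))
    f <- knn_feature(c(0, 0, 0), ctx, fr, K = 6)
    d <- sort(sqrt(ctx$x^2 + ctx$y^2 + ctx$z^2))[1:6]
    rho <- unname(f[seq(1, 16, by = 3)]); zz <- unname(f[seq(3, 18, by = 3)])
    expect_equal(sqrt(rho^2 + zz^2), d, tolerance = 1e-9)
  }
})

test_that("volume featurization has the documented shape and invariances", {
  fr <- identity_frame()
  one <- featurize_volume(tibble::tibble(object_id = 1L, cx = 5, cy = 5,
                                         cz = 3),
                          fr, q = 4, dl = 3, dz = 2, K = 5)
  v1 <- one$feature[[1]]
  expect_length(v1, 4 * 4 + 3 * 5)
  expect_true(all(v1 == 0))    # no context at all

  ds <- tiny_ds()
  v <- ds$volumes[[1]]
  pp <- preprocess_volume(v$red)
  obj <- dplyr::rename(v$gt$objects, object_id = id)
  f <- featurize_volume(obj, pp$frame, q = 8, K = 25, depth = 12)
  expect_equal(nrow(f), nrow(obj))
  lens <- vapply(f$feature, length, integer(1))
  expect_true(all(lens == 8 * 4 + 3 * 25))

  # rigid translation of the volume (points and frame together) leaves
  # features unchanged
  sh <- c(13, -7)
  fr2 <- pp$frame
  for (nm in c("O", "P_a", "P_p", "P_v", "P_d")) fr2[[nm]] <- fr2[[nm]] + sh
  obj2 <- dplyr::mutate(obj, cx = cx + sh[1], cy = cy + sh[2])
  f2 <- featurize_volume(obj2, fr2, q = 8, K = 25, depth = 12)
  expect_equal(feature_matrix(f2), feature_matrix(f), tolerance = 1e-9)
})
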