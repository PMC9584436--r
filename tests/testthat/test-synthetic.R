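test_that("layouts respect the head ellipsoid, exclusion radius and seed", {
  one <- generate_layout(layout_spec(n_neurons = 1, seed = 3))
  expect_equal(nrow(one), 1L)
  expect_lt((one$x / 75)^2 + (one$y / 40)^2, 1)

  a <- generate_layout(layout_spec(seed = 5))
  b <- generate_layout(layout_spec(seed = 5))
  expect_identical(a, b)

  dense <- generate_layout(layout_spec(n_neurons = 150, seed = 0))
  dmin <- min(dist(cbind(dense$x, dense$y)))
  expect_gte(dmin, 6)
})

test_that("deformation is identity at zero pose and isometric for pure rotation", {
  spec <- layout_spec(seed = 2)
  lay <- generate_layout(spec)
  id <- deform_layout(lay, 1, spec,
                      pose = list(bend_deg = 0, rot_deg = 0, shift = c(0, 0)))
  expect_equal(id$points$x, lay$x + spec$head_center[1])
  expect_equal(id$points$y, lay$y + spec$head_center[2])

  rot <- deform_layout(lay, 1, spec,
                       pose = list(bend_deg = 0, rot_deg = 37, shift = c(0, 0)))
  expect_equal(as.numeric(dist(cbind(rot$points$x, rot$points$y))),
               as.numeric(dist(cbind(lay$x, lay$y))), tolerance = 1e-10)
})

test_that("a 30 degree bend rotates the anterior half relative to the posterior", {
  spec <- layout_spec(seed = 4)
  lay <- generate_layout(spec)
  bent <- deform_layout(lay, 1, spec,
                        pose = list(bend_deg = 30, rot_deg = 0,
                                    shift = c(0, 0)))
  bx <- bent$points$x - spec$head_center[1]
  by <- bent$points$y - spec$head_center[2]
  half_angle <- function(sel) {
    # rotation angle best aligning canonical half onto its deformed image
    atan2(sum(lay$x[sel] * by[sel] - lay$y[sel] * bx[sel]),
          sum(lay$x[sel] * bx[sel] + lay$y[sel] * by[sel])) * 180 / pi
  }
  wt <- 0.2 * spec$head_axes[1]   # outside the smooth transition zone
  rel <- half_angle(lay$x > wt) - half_angle(lay$x < -wt)
  expect_equal(rel, 30, tolerance = 1)
})

test_that("rendered blobs peak at their centres and boxes track the z drift", {
  spec <- layout_spec(n_neurons = 1, background_noise_sigma = 0,
                      background_level = 0, head_glow = 0, body = FALSE,
                      interframe_shift_px = 0, seed = 7)
  lay <- generate_layout(spec)
  posed <- deform_layout(lay, 1, spec,
                         pose = list(bend_deg = 0, rot_deg = 0,
                                     shift = c(0, 0)))
  r <- render_volume(posed, spec, 1, lay)
  zf <- r$regions$z[which.max(r$regions$w)]  # any covered frame
  fr <- r$red[, , zf]
  pk <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk["col"]) - 1, round(posed$points$x), tolerance = 1)
  expect_equal(unname(pk["row"]) - 1, round(posed$points$y), tolerance = 1)

  # zero interframe shift: every object's per-frame boxes coincide
  spec0 <- layout_spec(interframe_shift_px = 0, seed = 8)
  ds0 <- generate_dataset(1, spec0)
  regs <- ds0$volumes[[1]]$gt$regions
  for (i in unique(regs$id)) {
    rr <- regs[regs$id == i, ]
    if (nrow(rr) < 2) next
    expect_true(all(rr$x == rr$x[1] & rr$y == rr$y[1] &
                      rr$w == rr$w[1] & rr$h == rr$h[1]))
  }
})

test_that("ground-truth region count equals the sum of blob z-spans", {
  spec <- layout_spec(n_neurons = 150, seed = 0)
  lay <- generate_layout(spec)
  ds <- generate_dataset(1, spec)
  expect_equal(nrow(ds$volumes[[1]]$gt$regions), sum(lay$z_span))
})

test_that("datasets are reproducible, ID-consistent, and obey both principles", {
  ds <- tiny_ds()
  expect_length(generate_dataset(1, layout_spec(seed = 1))$volumes, 1L)
  ids <- lapply(ds$volumes, function(v) sort(unique(v$gt$regions$id)))
  expect_true(all(vapply(ids, identical, logical(1), ids[[1]])))
  for (v in ds$volumes) {
    by_id <- split(v$gt$regions$z, v$gt$regions$id)
    for (zs in by_id) {
      expect_false(any(duplicated(zs)))                    # exclusion
      expect_equal(sort(zs), seq(min(zs), max(zs)))        # continuum
    }
  }
  ds2 <- generate_dataset(3, layout_spec(seed = 0), green = TRUE)
  expect_identical(ds2$volumes[[2]]$red, ds$volumes[[2]]$red)
})

test_that("extraction with true boxes recovers the generated activity", {
  ds <- tiny_ds()
  errs <- unlist(lapply(ds$volumes, function(v) {
    regs <- dplyr::rename(v$gt$regions, object_id = id)
    tr <- extract_activity(regs, v$red, v$green)
    truth <- ds$activity[ds$activity$volume == v$volume_index, ]
    m <- match(tr$object_id, truth$id)
    abs(tr$R - truth$activity[m]) / truth$activity[m]
  }))
  expect_lte(median(errs), 0.05)
})
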