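slpc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pca_normalize(test_leaf()$cloud)
    cache
  }
})

test_that("ordered PSF has the documented shape", {
  slpc <- slpc_fixture()
  sel <- select_slices(slice_cloud(slpc, 50), 7)
  psf <- build_ordered_psf(slpc, sel, tl = 2, tr = 2)
  expect_s3_class(psf, "psf")
  expect_true(psf$ordered)
  expect_length(psf$columns, 7)
  expect_true(all(vapply(psf$columns, nrow, 0L) == 7))
  expect_equal(nrow(psf_points(psf)), 49)
  # interior column members are actual cloud points
  P <- slpc$points
  for (j in 2:6) {
    col <- psf$columns[[j]]
    for (i in seq_len(nrow(col))) {
      d <- min(colSums((t(P) - col[i, ])^2))
      expect_lt(d, 1e-20)
    }
    # ordered left to right up to nearest-neighbour snap displacement:
    # snapping equally spaced seeds to cloud members can invert near-tied
    # neighbours by at most the local point spacing
    expect_true(all(diff(col[, 2]) > -1))
    expect_gt(cor(seq_len(nrow(col)), col[, 2]), 0.9)
  }
  # tip column collapses onto the tip point
  tipcol <- psf$columns[[7]]
  expect_true(all(apply(tipcol, 1, function(r) all(r == tipcol[1, ]))))
})

test_that("interior feature points are the band extremes", {
  slpc <- slpc_fixture()
  sel <- select_slices(slice_cloud(slpc, 50), 7)
  Ws <- attr(sel, "Ws")
  sl <- sel[[4]]
  tr <- interior_feature_points(sl, Ws)
  band <- sl$points[abs(sl$points[, 1] - sl$plane_x) <= Ws / 4, ,
                    drop = FALSE]
  expect_equal(tr$P_left[2], min(band[, 2]))
  expect_equal(tr$P_right[2], max(band[, 2]))
  expect_equal(tr$P_mid[3], max(band[, 3]))
})

test_that("a sparse central band widens with a warning", {
  sl <- list(index = 3L, plane_x = 0,
             points = cbind(c(-0.9, -0.8, 0.9), c(-1, 0, 1), c(0, 1, 0)))
  expect_warning(tr <- interior_feature_points(sl, Ws = 1), "widening")
  expect_equal(tr$P_left[2], -1)
})

test_that("unordered PSF projects interior slices onto their planes", {
  slpc <- slpc_fixture()
  sel <- select_slices(slice_cloud(slpc, 50), 7)
  psf <- build_unordered_psf(slpc, sel, tl = 2, tr = 2)
  expect_false(psf$ordered)
  for (j in 2:6) {
    col <- psf$columns[[j]]
    expect_true(all(col[, 1] == sel[[j]]$plane_x))
    expect_false(is.unsorted(col[, 2]))
    expect_equal(nrow(col), nrow(sel[[j]]$points))
  }
  # boundary columns match the ordered construction
  po <- build_ordered_psf(slpc, sel, tl = 2, tr = 2)
  expect_equal(psf$columns[[1]], po$columns[[1]])
  expect_equal(psf$columns[[7]], po$columns[[7]])
})

test_that("the test subset counts 10 columns of 9 points", {
  slpc <- slpc_fixture()
  ts <- build_test_subset(slpc, 10, 9)
  expect_true(ts$ordered)
  expect_length(ts$columns, 10)
  expect_true(all(vapply(ts$columns, nrow, 0L) == 9))
  expect_equal(nrow(psf_points(ts)), 90)
  expect_error(build_test_subset(slpc, 10, 8), "3 \\+ 2t")
})

test_that("feature seeds interpolate the polyline evenly", {
  tr <- leafnurbs:::feature_triple(c(0, -4, 0), c(0, 0, 2), c(0, 4, 0))
  seeds <- leafnurbs:::feature_seeds(tr, 2, 2)
  expect_equal(dim(seeds), c(7, 3))
  expect_equal(seeds[1, ], c(0, -4, 0))
  expect_equal(seeds[4, ], c(0, 0, 2))
  expect_equal(seeds[7, ], c(0, 4, 0))
  expect_equal(seeds[2, ], c(0, -4, 0) + (c(0, 0, 2) - c(0, -4, 0)) / 3)
  expect_equal(seeds[6, ], c(0, 0, 2) + 2 * (c(0, 4, 0) - c(0, 0, 2)) / 3)
})

test_that("tl/tr below 1 are rejected", {
  slpc <- slpc_fixture()
  sel <- select_slices(slice_cloud(slpc, 20), 5)
  expect_error(build_ordered_psf(slpc, sel, tl = 0, tr = 2), "at least 1")
})
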