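test_that("pca_normalize aligns the leaf axis with x and reports L", {
  leaf <- test_leaf()
  slpc <- pca_normalize(leaf$cloud)
  P <- slpc$points
  v <- apply(P, 2, var)
  expect_true(v[1] > v[2] && v[2] > v[3])
  expect_equal(slpc$L, diff(range(P[, 1])))
  expect_equal(colMeans(P), c(0, 0, 0), tolerance = 1e-8)
  expect_equal(det(slpc$rotation), 1, tolerance = 1e-12)
  expect_equal(slpc$rotation %*% t(slpc$rotation), diag(3),
               tolerance = 1e-12)
  # transform is recoverable: points = (input - translation) %*% t(R)
  expect_equal(P, sweep(cloud_points(leaf$cloud), 2, slpc$translation) %*%
                 t(slpc$rotation))
})

test_that("base sits at min(x) and the dome opens towards +z", {
  leaf <- test_leaf()
  slpc <- pca_normalize(leaf$cloud)
  P <- slpc$points
  band <- 0.05 * slpc$L
  wlo <- diff(range(P[P[, 1] <= min(P[, 1]) + band, 2]))
  whi <- diff(range(P[P[, 1] >= max(P[, 1]) - band, 2]))
  expect_lt(wlo, whi)   # narrow petiole end at min(x)
  # convex face towards +z: blade center higher than the blade edges
  center <- abs(P[, 2]) < 0.2 * max(abs(P[, 2]))
  edges <- abs(P[, 2]) > 0.8 * max(abs(P[, 2]))
  expect_gt(mean(P[center, 3]), mean(P[edges, 3]))
})

test_that("pose normalization undoes an arbitrary rigid transform", {
  base <- generate_leaf(leaf_spec(length = 50, n_points = 6000,
                                  noise_sd = 0.05, seed = 21))
  posed <- generate_leaf(leaf_spec(length = 50, n_points = 6000,
                                   noise_sd = 0.05, seed = 21,
                                   pose = list(rotation =
                                                 rotation_xyz(0.7, -1.2, 2.4),
                                               translation = c(40, -7, 13))))
  a <- pca_normalize(base$cloud)
  b <- pca_normalize(posed$cloud)
  expect_equal(a$points, b$points, tolerance = 1e-8)
})

test_that("degenerate clouds are rejected", {
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(pca_normalize(line), "degenerate")
  expect_error(pca_normalize(matrix(1, 3, 3)), "at least 4")
})

test_that("voxel downsampling hits the target within 10% and preserves extent", {
  leaf <- test_leaf()
  P <- cloud_points(leaf$cloud)
  for (tg in c(500, 2000, 8000)) {
    dc <- voxel_downsample(P, tg)
    n <- nrow(cloud_points(dc))
    expect_lte(abs(n - tg), 0.1 * tg)
    # centroids stay inside the original bounding box
    for (c3 in 1:3) {
      expect_gte(min(cloud_points(dc)[, c3]), min(P[, c3]))
      expect_lte(max(cloud_points(dc)[, c3]), max(P[, c3]))
    }
  }
})

test_that("voxel downsampling edge cases", {
  P <- matrix(rnorm(300), 100, 3)
  expect_warning(same <- voxel_downsample(P, 200), "exceeds")
  expect_equal(cloud_points(same), P)
  expect_error(voxel_downsample(P, 2), "at least 4")
  # jittered origins give different (but valid) subsets
  a <- voxel_downsample(P, 30, origin_jitter = c(0.1, 0.5, 0.9))
  b <- voxel_downsample(P, 30, origin_jitter = c(0.7, 0.2, 0.3))
  expect_false(identical(cloud_points(a), cloud_points(b)))
})
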