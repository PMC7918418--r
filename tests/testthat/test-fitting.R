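test_that("fit_config validates its arguments", {
  cfg <- fit_config()
  expect_equal(cfg$degrees, c(2L, 2L))
  expect_equal(cfg$n_ctrl, c(5L, 5L))
  expect_equal(cfg$mode, "algorithm1")
  expect_error(fit_config(degrees = c(3, 3), n_ctrl = c(3, 5)),
               "degree \\+ 1")
  expect_error(fit_config(mode = "nope"))
})

# a noiseless ordered PSF sampled from a known surface on parameter lines
sampled_psf <- function(surface, n_cols = 9, n_rows = 11,
                        equally = TRUE) {
  v <- seq(0, 1, length.out = n_cols)
  u <- seq(0, 1, length.out = n_rows)
  cols <- lapply(v, function(vv) evaluate_surface(surface, u, vv))
  leafnurbs:::new_psf(cols, ordered = TRUE)
}

bezier_patch <- function(seed = 1) {
  set.seed(seed)
  ctrl <- array(0, c(3, 3, 3))
  ctrl[, , 1] <- matrix(rep(c(0, 5, 10), 3), 3, 3)
  ctrl[, , 2] <- matrix(rep(c(0, 4, 8), each = 3), 3, 3)
  ctrl[, , 3] <- matrix(rnorm(9), 3, 3)
  spline_surface(c(2, 2), knot_vector(2), knot_vector(2), ctrl)
}

test_that("grid interpolation passes through every PSF point", {
  s <- bezier_patch(11)
  psf <- sampled_psf(s, 6, 7)
  cfg <- fit_config(mode = "interpolate",
                    parameterization = "equally_spaced")
  fit <- fit_surface_grid(psf, cfg)
  # reconstruct at the shared parameters: must hit the grid points
  cols <- psf$columns
  ubar <- seq(0, 1, length.out = 7)
  vbar <- seq(0, 1, length.out = 6)
  for (j in seq_along(cols)) {
    rec <- evaluate_surface(fit, ubar, rep(vbar[j], 7))
    expect_equal(rec, unname(cols[[j]]), tolerance = 1e-8)
  }
})

test_that("grid approximation recovers a spanning surface exactly", {
  s <- bezier_patch(12)
  psf <- sampled_psf(s, 9, 11)
  cfg <- fit_config(n_ctrl = c(3, 3), mode = "approximate",
                    parameterization = "equally_spaced")
  fit <- fit_surface_grid(psf, cfg)
  uv <- expand.grid(u = seq(0, 1, 0.05), v = seq(0, 1, 0.05))
  err <- max(abs(evaluate_surface(fit, uv$u, uv$v) -
                   evaluate_surface(s, uv$u, uv$v)))
  expect_lt(err, 1e-6)
})

test_that("algorithm1 fits ordered and unordered PSFs", {
  slpc <- pca_normalize(test_leaf()$cloud)
  sel <- select_slices(slice_cloud(slpc, 50), 7)
  cfg <- fit_config()
  for (psf in list(build_ordered_psf(slpc, sel),
                   build_unordered_psf(slpc, sel))) {
    fit <- fit_surface_algorithm1(psf, cfg)
    expect_s3_class(fit, "spline_surface")
    expect_equal(dim(fit$control), c(5, 5, 3))
    expect_false(is.unsorted(as.numeric(fit$knots_u)))
    expect_false(is.unsorted(as.numeric(fit$knots_v)))
    # fitted surface stays within a sane multiple of the cloud extent
    g <- evaluate_surface_grid(fit, seq(0, 1, 0.1), seq(0, 1, 0.1))
    expect_lt(max(abs(g)), 2 * max(abs(slpc$points)))
  }
})

test_that("algorithm1 averaged knot vectors are clamped and non-decreasing", {
  slpc <- pca_normalize(test_leaf()$cloud)
  sel <- select_slices(slice_cloud(slpc, 30), 9)
  fit <- fit_surface_algorithm1(build_unordered_psf(slpc, sel),
                                fit_config(n_ctrl = c(5, 7)))
  for (kv in list(fit$knots_u, fit$knots_v)) {
    k <- as.numeric(kv)
    p <- attr(kv, "degree")
    expect_equal(k[seq_len(p + 1)], rep(0, p + 1))
    expect_equal(rev(k)[seq_len(p + 1)], rep(1, p + 1))
    expect_false(is.unsorted(k))
  }
})

test_that("grid modes reject unordered PSFs and oversized nets", {
  slpc <- pca_normalize(test_leaf()$cloud)
  sel <- select_slices(slice_cloud(slpc, 50), 7)
  up <- build_unordered_psf(slpc, sel)
  expect_error(fit_surface_grid(up, fit_config(mode = "interpolate")),
               "ordered")
  op <- build_ordered_psf(slpc, sel)       # 7 x 7 grid
  expect_error(fit_surface_grid(op, fit_config(n_ctrl = c(9, 5),
                                               mode = "approximate")),
               "exceeds")
  expect_error(fit_surface_algorithm1(op, fit_config(n_ctrl = c(9, 5))),
               "fewer than")
})
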