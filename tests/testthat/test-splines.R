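test_that("clamped knot vectors are built and validated", {
  kv <- knot_vector(2, c(0.3, 0.6))
  expect_s3_class(kv, "knot_vector")
  expect_equal(as.numeric(kv), c(0, 0, 0, 0.3, 0.6, 1, 1, 1))
  expect_equal(attr(kv, "degree"), 2L)
  expect_error(knot_vector(2, c(0.6, 0.3)), "non-decreasing")
  expect_error(knot_vector(2, 1.2), "interior knots")
})

test_that("basis functions match the literal recursion oracle", {
  set.seed(1)
  for (p in 0:3) {
    kv <- knot_vector(p, sort(runif(3)))
    nb <- length(kv) - p - 1L
    for (u in c(0, runif(10), 1)) {
      for (i in seq_len(nb) - 1L) {
        expect_equal(basis_function(i, p, u, kv),
                     oracle_basis(i + 1L, p, u, as.numeric(kv)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("basis functions form a partition of unity", {
  kv <- knot_vector(3, c(0.2, 0.2, 0.5, 0.9))
  nb <- length(kv) - 4L
  for (u in c(0, 0.1, 0.2, 0.5, 0.77, 0.9, 1)) {
    vals <- vapply(seq_len(nb) - 1L, basis_function, 0, p = 3, u = u,
                   knots = kv)
    expect_equal(sum(vals), 1, tolerance = 1e-12)
    expect_true(all(vals >= 0))
  }
})

test_that("basis_matrix rows agree with basis_function and sum to one", {
  kv <- knot_vector(2, c(0.25, 0.5, 0.75))
  u <- seq(0, 1, length.out = 23)
  B <- basis_matrix(u, kv)
  expect_equal(rowSums(B), rep(1, length(u)), tolerance = 1e-12)
  for (k in seq_along(u)) for (i in seq_len(ncol(B)))
    expect_equal(B[k, i], basis_function(i - 1L, 2, u[k], kv),
                 tolerance = 1e-12)
})

test_that("derivative basis values match finite differences", {
  kv <- knot_vector(3, c(0.3, 0.7))
  h <- 1e-6
  for (u in c(0.1, 0.45, 0.83)) {
    sp <- leafnurbs:::find_span(u, kv)
    D <- leafnurbs:::ders_basis_funs(sp, u, kv, 2L)
    f0 <- leafnurbs:::basis_funs(sp, u, kv)
    fp <- leafnurbs:::basis_funs(sp, u + h, kv)
    fm <- leafnurbs:::basis_funs(sp, u - h, kv)
    expect_equal(D[1, ], f0, tolerance = 1e-12)
    expect_equal(D[2, ], (fp - fm) / (2 * h), tolerance = 1e-5)
    expect_equal(D[3, ], (fp - 2 * f0 + fm) / h^2, tolerance = 1e-3)
  }
})

test_that("parameterization methods behave as documented", {
  pts <- cbind(c(0, 1, 3, 6), 0, 0)
  expect_equal(parameterize(pts, "chord_length"), c(0, 1, 3, 6) / 6)
  cp <- parameterize(pts, "centripetal")
  expect_equal(cp, cumsum(c(0, sqrt(c(1, 2, 3)))) /
                 sum(sqrt(c(1, 2, 3))))
  expect_equal(parameterize(pts, "equally_spaced"), c(0, 1, 2, 3) / 3)
  dup <- pts[c(1, 2, 2, 3, 4), ]
  expect_warning(pd <- parameterize(dup, "chord_length"), "coincident")
  expect_true(all(diff(pd) > 0))
  same <- matrix(1, 4, 3)
  expect_warning(ps <- parameterize(same), "coincide")
  expect_equal(ps, c(0, 1, 2, 3) / 3)
})

test_that("knot placement satisfies Schoenberg-Whitney (nonsingular fits)", {
  set.seed(2)
  for (rep in 1:5) {
    m <- sample(8:20, 1)
    pts <- cbind(sort(runif(m)), runif(m), runif(m))
    params <- parameterize(pts)
    for (n_ctrl in c(4, 5, m)) {
      kv <- knots_from_params(params, 3, n_ctrl)
      expect_length(as.numeric(kv), n_ctrl + 4)
      expect_false(is.unsorted(as.numeric(kv)))
      B <- basis_matrix(params, kv)
      expect_equal(qr(B)$rank, n_ctrl)
    }
  }
})

test_that("curve interpolation passes through every point", {
  set.seed(3)
  pts <- cbind(seq(0, 10, length.out = 7), rnorm(7), rnorm(7))
  cv <- fit_curve_interpolate(pts, 3)
  rec <- evaluate_curve(cv, attr(cv, "params"))
  expect_equal(rec, pts, tolerance = 1e-9)
})

test_that("curve approximation pins endpoints and matches the normal-equations oracle", {
  set.seed(4)
  pts <- cbind(seq(0, 10, length.out = 15), sin(1:15), cos(1:15))
  cv <- fit_curve_approximate(pts, 3, 6)
  expect_equal(cv$control[1, ], pts[1, ])
  expect_equal(cv$control[6, ], pts[15, ])
  oc <- oracle_lsq_curve(pts, attr(cv, "params"), 3, cv$knots, 6)
  expect_equal(max(abs(cv$control - oc)) / max(abs(oc)), 0,
               tolerance = 1e-8)
})

test_that("approximation with n_ctrl = n reduces to interpolation", {
  set.seed(5)
  pts <- cbind(1:6, rnorm(6), rnorm(6))
  a <- fit_curve_approximate(pts, 2, 6)
  b <- fit_curve_interpolate(pts, 2)
  expect_equal(a$control, b$control, tolerance = 1e-10)
})

test_that("a column of identical points collapses without error", {
  pts <- matrix(rep(c(1, 2, 3), each = 8), 8, 3)
  cv <- fit_curve_approximate(pts, 2, 4)
  expect_equal(cv$control, matrix(c(1, 2, 3), 4, 3, byrow = TRUE))
  expect_equal(evaluate_curve(cv, c(0, 0.37, 1)),
               matrix(c(1, 2, 3), 3, 3, byrow = TRUE), tolerance = 1e-12)
})

test_that("surface evaluation matches the naive double-summation oracle", {
  set.seed(6)
  ctrl <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  W <- matrix(runif(20, 0.5, 2), 4, 5)
  s <- spline_surface(c(2, 2), knot_vector(2, 0.5),
                      knot_vector(2, c(0.3, 0.7)), ctrl, W)
  for (k in 1:20) {
    u <- runif(1); v <- runif(1)
    expect_equal(as.numeric(evaluate_surface(s, u, v)),
                 oracle_surface_point(s, u, v), tolerance = 1e-12)
  }
  # corners interpolate the corner control points (clamped knots)
  expect_equal(as.numeric(evaluate_surface(s, 0, 0)), ctrl[1, 1, ],
               tolerance = 1e-12)
  expect_equal(as.numeric(evaluate_surface(s, 1, 1)), ctrl[4, 5, ],
               tolerance = 1e-12)
})

test_that("grid evaluation agrees with pointwise evaluation", {
  set.seed(7)
  ctrl <- array(rnorm(3 * 4 * 3), c(3, 4, 3))
  W <- matrix(runif(12, 0.2, 3), 3, 4)
  s <- spline_surface(c(2, 2), knot_vector(2), knot_vector(2, 0.4), ctrl, W)
  u <- seq(0, 1, length.out = 7); v <- seq(0, 1, length.out = 9)
  G <- evaluate_surface_grid(s, u, v)
  for (i in seq_along(u)) for (j in seq_along(v))
    expect_equal(G[i, j, ], as.numeric(evaluate_surface(s, u[i], v[j])),
                 tolerance = 1e-12)
})

test_that("all-ones weights reproduce the non-rational surface", {
  set.seed(8)
  ctrl <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  s1 <- spline_surface(c(3, 3), knot_vector(3), knot_vector(3), ctrl)
  s2 <- spline_surface(c(3, 3), knot_vector(3), knot_vector(3), ctrl,
                       matrix(1, 4, 4))
  uv <- runif(10)
  expect_equal(evaluate_surface(s1, uv, rev(uv)),
               evaluate_surface(s2, uv, rev(uv)), tolerance = 1e-14)
})

test_that("surface derivatives match finite differences (rational case)", {
  set.seed(9)
  ctrl <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  W <- matrix(runif(20, 0.5, 2), 4, 5)
  s <- spline_surface(c(2, 2), knot_vector(2, 0.5),
                      knot_vector(2, c(0.3, 0.7)), ctrl, W)
  h <- 1e-5
  for (uv in list(c(0.2, 0.6), c(0.45, 0.31), c(0.8, 0.9))) {
    u <- uv[1]; v <- uv[2]
    dd <- leafnurbs:::surface_ders(s, u, v)
    f <- function(a, b) as.numeric(evaluate_surface(s, a, b))
    expect_equal(dd$S, f(u, v), tolerance = 1e-12)
    expect_equal(dd$Su, (f(u + h, v) - f(u - h, v)) / (2 * h),
                 tolerance = 1e-6)
    expect_equal(dd$Sv, (f(u, v + h) - f(u, v - h)) / (2 * h),
                 tolerance = 1e-6)
    expect_equal(dd$Suu, (f(u + h, v) - 2 * f(u, v) + f(u - h, v)) / h^2,
                 tolerance = 1e-4)
    expect_equal(dd$Svv, (f(u, v + h) - 2 * f(u, v) + f(u, v - h)) / h^2,
                 tolerance = 1e-4)
    expect_equal(dd$Suv,
                 (f(u + h, v + h) - f(u + h, v - h) -
                    f(u - h, v + h) + f(u - h, v - h)) / (4 * h^2),
                 tolerance = 1e-4)
  }
})

test_that("surfaces survive a JSON round trip exactly", {
  set.seed(10)
  ctrl <- array(rnorm(3 * 5 * 3), c(3, 5, 3))
  W <- matrix(runif(15, 0.3, 4), 3, 5)
  s <- spline_surface(c(2, 2), knot_vector(2), knot_vector(2, c(0.4, 0.6)),
                      ctrl, W)
  path <- withr::local_tempfile(fileext = ".json")
  write_surface_json(s, path)
  s2 <- read_surface_json(path)
  expect_equal(s2$control, s$control)
  expect_equal(s2$weights, s$weights)
  expect_equal(as.numeric(s2$knots_u), as.numeric(s$knots_u))
  uv <- seq(0, 1, 0.1)
  expect_equal(evaluate_surface(s2, uv, rev(uv)),
               evaluate_surface(s, uv, rev(uv)))
})

test_that("invalid surface construction is rejected", {
  ctrl <- array(0, c(3, 3, 3))
  expect_error(spline_surface(c(2, 2), knot_vector(2), knot_vector(2, 0.5),
                              ctrl), "inconsistent")
  expect_error(spline_surface(c(2, 2), knot_vector(2), knot_vector(2),
                              ctrl, matrix(0, 3, 3)), "positive")
})
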