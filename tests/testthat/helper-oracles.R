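# Independent reference implementations used to cross-check the package's
# vectorized code paths. Deliberately naive and literal.

# one basis function by the textbook recursion, written without any of the
# package's span machinery
oracle_basis <- function(i, p, u, knots) {
  m <- length(knots)
  if (p == 0) {
    last_span <- max(which(knots < knots[m]))
    if (u >= knots[m] && i == last_span) return(1)
    return(as.numeric(u >= knots[i] && u < knots[i + 1]))
  }
  a <- 0
  if (knots[i + p] > knots[i])
    a <- (u - knots[i]) / (knots[i + p] - knots[i]) *
      oracle_basis(i, p - 1, u, knots)
  b <- 0
  if (knots[i + p + 1] > knots[i + 1])
    b <- (knots[i + p + 1] - u) / (knots[i + p + 1] - knots[i + 1]) *
      oracle_basis(i + 1, p - 1, u, knots)
  a + b
}

# rational surface point by the naive double summation over every basis
# product
oracle_surface_point <- function(surface, u, v) {
  n_u <- dim(surface$control)[1]
  n_v <- dim(surface$control)[2]
  p <- surface$degrees[1]; q <- surface$degrees[2]
  num <- c(0, 0, 0); den <- 0
  for (i in seq_len(n_u)) for (j in seq_len(n_v)) {
    b <- oracle_basis(i, p, u, surface$knots_u) *
      oracle_basis(j, q, v, surface$knots_v) * surface$weights[i, j]
    num <- num + b * surface$control[i, j, ]
    den <- den + b
  }
  num / den
}

# endpoint-pinned least-squares curve fit solved via the normal equations
# (the package uses QR); returns the control points
oracle_lsq_curve <- function(points, params, degree, knots, n_ctrl) {
  B <- leafnurbs::basis_matrix(params, knots)
  m <- nrow(points)
  R <- points - outer(B[, 1], points[1, ]) -
    outer(B[, n_ctrl], points[m, ])
  Bi <- B[, 2:(n_ctrl - 1), drop = FALSE]
  mid <- solve(crossprod(Bi), crossprod(Bi, R))
  rbind(points[1, ], mid, points[m, ])
}

# dense-grid minimum distance (projection oracle)
oracle_grid_distance <- function(surface, G, n = 200) {
  uv <- seq(0, 1, length.out = n)
  g <- leafnurbs::evaluate_surface_grid(surface, uv, uv)
  min(sqrt((g[, , 1] - G[1])^2 + (g[, , 2] - G[2])^2 +
             (g[, , 3] - G[3])^2))
}

# small deterministic rigid transformations for invariance tests
rotation_xyz <- function(ax, ay, az) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3)
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

# a standard mid-size synthetic leaf shared by several test files
test_leaf <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_leaf(leaf_spec(length = 55, n_points = 12000,
                                        noise_sd = 0.1, seed = 7))
    cache
  }
})
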