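#' B-spline and NURBS primitives
#'
#' Low-level spline machinery: Cox-de Boor basis functions, clamped knot
#' vectors, chord-length/centripetal/equally-spaced parameterization, global
#' curve interpolation and least-squares approximation, and tensor-product
#' surface evaluation in both non-rational (B-spline) and rational (NURBS)
#' form. The parameter domain is always [0, 1] and knot vectors are clamped:
#' the first and last degree+1 knots are pinned to 0 and 1 respectively, so
#' curves and surfaces interpolate their boundary control points.
#'
#' @name splines_core
#' @keywords internal
NULL

## ---- knot vectors -----------------------------------------------------

#' Construct a clamped knot vector
#'
#' @param degree spline degree (non-negative integer).
#' @param interior numeric vector of interior knots in (0, 1), non-decreasing.
#' @return numeric knot vector of class `knot_vector` with attribute `degree`.
#' @export
knot_vector <- function(degree, interior = numeric(0)) {
  stopifnot(degree >= 0)
  if (length(interior) && (any(interior < 0) || any(interior > 1)))
    stop("interior knots must lie in [0, 1]")
  if (is.unsorted(interior)) stop("interior knots must be non-decreasing")
  kv <- c(rep(0, degree + 1), as.numeric(interior), rep(1, degree + 1))
  structure(kv, degree = as.integer(degree), class = "knot_vector")
}

#' @export
print.knot_vector <- function(x, ...) {
  cat("Clamped knot vector, degree", attr(x, "degree"),
      "(", length(x) - attr(x, "degree") - 1L, "basis functions )\n")
  print(as.numeric(x))
  invisible(x)
}

n_basis <- function(knots) {
  length(knots) - attr(knots, "degree") - 1L
}

validate_knots <- function(knots) {
  p <- attr(knots, "degree")
  kv <- as.numeric(knots)
  if (is.unsorted(kv)) stop("knot vector must be non-decreasing")
  if (any(kv[seq_len(p + 1)] != 0) || any(rev(kv)[seq_len(p + 1)] != 1))
    stop("knot vector must be clamped to [0, 1]")
  invisible(TRUE)
}

# Knot span index (0-based, Piegl-Tiller A2.1 convention): largest i with
# knots[i+1] <= u, restricted to [p, n]. At u = 1 returns the last non-empty
# span so evaluation at the right endpoint is defined.
find_span <- function(u, knots) {
  p <- attr(knots, "degree")
  kv <- as.numeric(knots)
  n <- length(kv) - p - 2L  # last control index, 0-based
  if (u >= kv[n + 2L]) return(n)
  if (u <= kv[p + 1L]) return(p)
  findInterval(u, kv, rightmost.closed = FALSE) - 1L
}

## ---- basis functions --------------------------------------------------

#' Evaluate a single B-spline basis function
#'
#' Cox-de Boor recursion for \eqn{N_{i,p}(u)}; 0/0 terms are treated as 0.
#' Spans are half-open except the final span, which is closed at u = 1.
#'
#' @param i 0-based basis-function index.
#' @param p degree.
#' @param u parameter value in [0, 1].
#' @param knots a `knot_vector` (its own degree attribute is ignored; `p` rules).
#' @return scalar basis-function value.
#' @export
basis_function <- function(i, p, u, knots) {
  kv <- as.numeric(knots)
  if (i < 0 || i + p + 1L > length(kv) - 1L)
    stop("basis-function index out of range for this knot vector")
  if (u < 0 || u > 1) stop("parameter u must lie in [0, 1]")
  # right-endpoint closure: N_{i,0} at u = 1 is 1 on the last non-empty span
  deg0 <- function(j) {
    lo <- kv[j + 1L]; hi <- kv[j + 2L]
    if (u >= lo && u < hi) return(1)
    if (u == 1 && hi == 1 && lo < hi) return(1)
    0
  }
  rec <- function(j, q) {
    if (q == 0L) return(deg0(j))
    left <- 0
    d1 <- kv[j + q + 1L] - kv[j + 1L]
    if (d1 > 0) left <- (u - kv[j + 1L]) / d1 * rec(j, q - 1L)
    right <- 0
    d2 <- kv[j + q + 2L] - kv[j + 2L]
    if (d2 > 0) right <- (kv[j + q + 2L] - u) / d2 * rec(j + 1L, q - 1L)
    left + right
  }
  rec(as.integer(i), as.integer(p))
}

# Non-zero basis functions at u (Piegl-Tiller A2.2). Returns the p+1 values
# N_{span-p,p}(u), ..., N_{span,p}(u).
basis_funs <- function(span, u, knots) {
  p <- attr(knots, "degree")
  kv <- as.numeric(knots)
  N <- numeric(p + 1); N[1] <- 1
  left <- numeric(p); right <- numeric(p)
  if (p == 0L) return(N)
  for (j in seq_len(p)) {
    left[j] <- u - kv[span + 1L - j + 1L]
    right[j] <- kv[span + j + 1L] - u
    saved <- 0
    for (r in seq_len(j)) {
      den <- right[r] + left[j - r + 1L]
      temp <- if (den != 0) N[r] / den else 0
      N[r] <- saved + right[r] * temp
      saved <- left[j - r + 1L] * temp
    }
    N[j + 1L] <- saved
  }
  N
}

# Basis functions and derivatives up to order d (Piegl-Tiller A2.3).
# Returns (d+1) x (p+1) matrix; row k+1 holds k-th derivatives.
ders_basis_funs <- function(span, u, knots, d) {
  p <- attr(knots, "degree")
  kv <- as.numeric(knots)
  d <- min(d, p)
  ndu <- matrix(0, p + 1, p + 1)
  ndu[1, 1] <- 1
  left <- numeric(p + 1); right <- numeric(p + 1)
  for (j in seq_len(p)) {
    left[j + 1] <- u - kv[span + 1L - j + 1L]
    right[j + 1] <- kv[span + j + 1L] - u
    saved <- 0
    for (r in 0:(j - 1)) {
      ndu[j + 1, r + 1] <- right[r + 2] + left[j - r + 1]
      temp <- ndu[r + 1, j] / ndu[j + 1, r + 1]
      ndu[r + 1, j + 1] <- saved + right[r + 2] * temp
      saved <- left[j - r + 1] * temp
    }
    ndu[j + 1, j + 1] <- saved
  }
  ders <- matrix(0, d + 1, p + 1)
  ders[1, ] <- ndu[, p + 1]
  if (d == 0) return(ders)
  a <- matrix(0, 2, p + 1)
  for (r in 0:p) {
    s1 <- 0L; s2 <- 1L
    a[1, 1] <- 1
    for (k in seq_len(d)) {
      dd <- 0
      rk <- r - k; pk <- p - k
      if (r >= k) {
        a[s2 + 1, 1] <- a[s1 + 1, 1] / ndu[pk + 2, rk + 1]
        dd <- a[s2 + 1, 1] * ndu[rk + 1, pk + 1]
      }
      j1 <- if (rk >= -1) 1L else -rk
      j2 <- if (r - 1 <= pk) k - 1L else p - r
      if (j1 <= j2) for (j in j1:j2) {
        a[s2 + 1, j + 1] <- (a[s1 + 1, j + 1] - a[s1 + 1, j]) /
          ndu[pk + 2, rk + j + 1]
        dd <- dd + a[s2 + 1, j + 1] * ndu[rk + j + 1, pk + 1]
      }
      if (r <= pk) {
        a[s2 + 1, k + 1] <- -a[s1 + 1, k] / ndu[pk + 2, r + 1]
        dd <- dd + a[s2 + 1, k + 1] * ndu[r + 1, pk + 1]
      }
      ders[k + 1, r + 1] <- dd
      tmp <- s1; s1 <- s2; s2 <- tmp
    }
  }
  r <- p
  for (k in seq_len(d)) {
    ders[k + 1, ] <- ders[k + 1, ] * r
    r <- r * (p - k)
  }
  ders
}

#' Collocation matrix of B-spline basis functions
#'
#' @param u numeric vector of parameters in [0, 1].
#' @param knots a `knot_vector`.
#' @return `length(u)` x `n_basis(knots)` dense matrix of basis values.
#' @export
basis_matrix <- function(u, knots) {
  p <- attr(knots, "degree")
  nb <- n_basis(knots)
  B <- matrix(0, length(u), nb)
  for (k in seq_along(u)) {
    sp <- find_span(u[k], knots)
    B[k, (sp - p + 1L):(sp + 1L)] <- basis_funs(sp, u[k], knots)
  }
  B
}

## ---- parameterization and knot placement ------------------------------

#' Assign parameter values to an ordered point sequence
#'
#' @param points numeric matrix (n x 3), ordered along the curve.
#' @param method `"chord_length"` (default), `"centripetal"`, or
#'   `"equally_spaced"`.
#' @return strictly increasing numeric vector in [0, 1], endpoints 0 and 1.
#'   Coincident consecutive points under chord-based methods contribute the
#'   mean positive increment instead (with a warning), falling back to
#'   equal spacing when all points coincide.
#' @export
parameterize <- function(points,
                         method = c("chord_length", "centripetal",
                                    "equally_spaced")) {
  method <- match.arg(method)
  points <- as_xyz(points)
  n <- nrow(points)
  if (n < 2) stop("parameterization needs at least 2 points")
  if (method == "equally_spaced") return(seq(0, 1, length.out = n))
  d <- sqrt(rowSums((points[-1, , drop = FALSE] -
                     points[-n, , drop = FALSE])^2))
  if (method == "centripetal") d <- sqrt(d)
  if (all(d == 0)) {
    warning("all points coincide; falling back to equally spaced parameters")
    return(seq(0, 1, length.out = n))
  }
  if (any(d == 0)) {
    warning("coincident consecutive points; zero chords replaced by mean step")
    d[d == 0] <- mean(d[d > 0])
  }
  u <- c(0, cumsum(d))
  u / u[n]
}

#' Derive a clamped knot vector from parameter values
#'
#' Knot averaging when `n_ctrl` equals the number of parameters
#' (interpolation), density-based placement otherwise (approximation), so the
#' Schoenberg-Whitney conditions hold and collocation systems are nonsingular.
#'
#' @param params parameter vector from [parameterize()].
#' @param degree spline degree.
#' @param n_ctrl number of control points.
#' @return a `knot_vector` of length `n_ctrl + degree + 1`.
#' @export
knots_from_params <- function(params, degree, n_ctrl) {
  r <- length(params) - 1L          # last data index, 0-based
  n <- n_ctrl - 1L                  # last control index, 0-based
  p <- as.integer(degree)
  if (n_ctrl < p + 1) stop("n_ctrl must be at least degree + 1")
  if (n_ctrl > length(params))
    stop("n_ctrl cannot exceed the number of parameters")
  if (n == p) return(knot_vector(p))  # Bezier: no interior knots
  if (n_ctrl == length(params)) {
    # interpolation: averaging of consecutive parameters
    interior <- vapply(seq_len(n - p), function(j)
      mean(params[(j + 1):(j + p)]), numeric(1))
  } else {
    # approximation: Piegl-Tiller style density placement
    d <- (r + 1) / (n - p + 1)
    interior <- vapply(seq_len(n - p), function(j) {
      i <- floor(j * d)
      alpha <- j * d - i
      (1 - alpha) * params[i] + alpha * params[i + 1]
    }, numeric(1))
  }
  knot_vector(p, interior)
}

## ---- curves ------------------------------------------------------------

new_spline_curve <- function(degree, knots, control, weights = NULL) {
  structure(list(degree = as.integer(degree), knots = knots,
                 control = control, weights = weights),
            class = "spline_curve")
}

#' @export
print.spline_curve <- function(x, ...) {
  cat("B-spline curve: degree", x$degree, "with", nrow(x$control),
      "control points\n")
  invisible(x)
}

#' Evaluate a spline curve
#'
#' @param curve a `spline_curve`.
#' @param u numeric vector of parameters in [0, 1].
#' @return `length(u)` x 3 matrix of points.
#' @export
evaluate_curve <- function(curve, u) {
  B <- basis_matrix(u, curve$knots)
  if (!is.null(curve$weights)) {
    Bw <- B * rep(curve$weights, each = nrow(B))
    (Bw %*% curve$control) / rowSums(Bw)
  } else {
    B %*% curve$control
  }
}

#' Global curve interpolation
#'
#' Fits a clamped degree-`degree` B-spline curve through every input point:
#' chord-length (default) parameters, averaged knots, and a square
#' collocation solve.
#'
#' @param points n x 3 matrix of ordered points, n >= degree + 1.
#' @param degree spline degree.
#' @param parameterization method passed to [parameterize()].
#' @return a `spline_curve` with n control points.
#' @export
fit_curve_interpolate <- function(points, degree,
                                  parameterization = "chord_length") {
  points <- as_xyz(points)
  n <- nrow(points)
  if (n < degree + 1) stop("need at least degree + 1 points to interpolate")
  params <- parameterize(points, parameterization)
  knots <- knots_from_params(params, degree, n)
  B <- basis_matrix(params, knots)
  ctrl <- tryCatch(solve(B, points), error = function(e)
    stop("singular interpolation system: coincident or degenerate ",
         "point configuration (", conditionMessage(e), ")"))
  cv <- new_spline_curve(degree, knots, ctrl)
  attr(cv, "params") <- params
  cv
}

#' Least-squares curve approximation with interpolated endpoints
#'
#' Fits a degree-`degree` curve with `n_ctrl` control points; the first and
#' last control points are pinned to the first and last data points and the
#' interior control points solve the linear least-squares problem (via QR,
#' not normal equations). With `n_ctrl` equal to the number of points this
#' reduces to [fit_curve_interpolate()]. A column of (numerically) identical
#' points collapses to a curve whose control points all equal that point.
#'
#' @param points n x 3 matrix of ordered points.
#' @param degree spline degree.
#' @param n_ctrl number of control points, degree + 1 <= n_ctrl <= n.
#' @param parameterization method passed to [parameterize()].
#' @return a `spline_curve` with `n_ctrl` control points; attribute `params`
#'   carries the parameter values used.
#' @export
fit_curve_approximate <- function(points, degree, n_ctrl,
                                  parameterization = "chord_length") {
  points <- as_xyz(points)
  r <- nrow(points) - 1L
  if (n_ctrl < degree + 1) stop("n_ctrl must be at least degree + 1")
  if (n_ctrl > r + 1) stop("n_ctrl cannot exceed the number of points")
  # degenerate column of identical points: collapsed (Bezier-like) curve
  rng <- apply(points, 2, function(z) diff(range(z)))
  if (all(rng < 1e-12)) {
    params <- seq(0, 1, length.out = r + 1)
    knots <- knots_from_params(params, degree, n_ctrl)
    ctrl <- matrix(points[1, ], n_ctrl, 3, byrow = TRUE)
    cv <- new_spline_curve(degree, knots, ctrl)
    attr(cv, "params") <- params
    return(cv)
  }
  if (n_ctrl == r + 1) return(fit_curve_interpolate(points, degree,
                                                    parameterization))
  params <- parameterize(points, parameterization)
  knots <- knots_from_params(params, degree, n_ctrl)
  n <- n_ctrl - 1L
  B <- basis_matrix(params, knots)
  ctrl <- matrix(0, n_ctrl, 3)
  ctrl[1, ] <- points[1, ]
  ctrl[n_ctrl, ] <- points[r + 1, ]
  if (n_ctrl > 2) {
    # subtract pinned-endpoint contributions, solve for interior controls
    rhs <- points[2:r, , drop = FALSE] -
      outer(B[2:r, 1], points[1, ]) -
      outer(B[2:r, n_ctrl], points[r + 1, ])
    Nmat <- B[2:r, 2:n, drop = FALSE]
    qrN <- qr(Nmat)
    if (qrN$rank < ncol(Nmat))
      stop("rank-deficient least-squares design: too few distinct ",
           "parameters for the requested control points")
    ctrl[2:n, ] <- qr.coef(qrN, rhs)
  }
  cv <- new_spline_curve(degree, knots, ctrl)
  attr(cv, "params") <- params
  cv
}

## ---- surfaces ----------------------------------------------------------

#' Construct a tensor-product spline surface
#'
#' @param degrees integer pair (p, q): degree across slices (u) and along the
#'   leaf axis (v).
#' @param knots_u,knots_v `knot_vector`s for the two directions.
#' @param control numeric array `n_u x n_v x 3` of control points; index 1
#'   runs in u, index 2 in v.
#' @param weights `n_u x n_v` matrix of positive weights; all ones (the
#'   default) gives the non-rational B-spline form.
#' @return an object of class `spline_surface`.
#' @export
spline_surface <- function(degrees, knots_u, knots_v, control,
                           weights = NULL) {
  stopifnot(length(dim(control)) == 3, dim(control)[3] == 3)
  nu <- dim(control)[1]; nv <- dim(control)[2]
  validate_knots(knots_u); validate_knots(knots_v)
  if (n_basis(knots_u) != nu || n_basis(knots_v) != nv)
    stop("knot vector lengths inconsistent with the control net")
  if (is.null(weights)) weights <- matrix(1, nu, nv)
  if (any(weights <= 0)) stop("all weights must be positive")
  structure(list(degrees = as.integer(degrees), knots_u = knots_u,
                 knots_v = knots_v, control = control,
                 weights = weights),
            class = "spline_surface")
}

is_rational <- function(s) any(s$weights != 1)

#' @export
print.spline_surface <- function(x, ...) {
  cat(sprintf("%s surface of degree (%d,%d) with %d x %d control points\n",
              if (is_rational(x)) "NURBS" else "B-spline",
              x$degrees[1], x$degrees[2],
              dim(x$control)[1], dim(x$control)[2]))
  invisible(x)
}

#' Evaluate a spline surface at parameter pairs
#'
#' Rational tensor-product evaluation; with all weights equal to 1 this is
#' the plain B-spline double sum.
#'
#' @param surface a `spline_surface`.
#' @param u,v numeric vectors of equal length (recycled scalar allowed) with
#'   values in [0, 1].
#' @return `length(u)` x 3 matrix of surface points.
#' @export
evaluate_surface <- function(surface, u, v) {
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  Bu <- basis_matrix(u, surface$knots_u)
  Bv <- basis_matrix(v, surface$knots_v)
  W <- surface$weights
  out <- matrix(0, n, 3)
  wsum <- numeric(n)
  for (k in seq_len(n)) {
    blend <- (Bu[k, ] %o% Bv[k, ]) * W
    wsum[k] <- sum(blend)
    for (c3 in 1:3) out[k, c3] <- sum(blend * surface$control[, , c3])
  }
  out / wsum
}

#' Evaluate a spline surface on a full parameter grid
#'
#' Fast path for meshing and dense-grid distance queries: evaluates at every
#' combination of `u` and `v` with two basis-matrix multiplications per
#' coordinate.
#'
#' @param surface a `spline_surface`.
#' @param u,v numeric vectors of parameters.
#' @return array `length(u) x length(v) x 3` of surface points.
#' @export
evaluate_surface_grid <- function(surface, u, v) {
  Bu <- basis_matrix(u, surface$knots_u)
  Bv <- basis_matrix(v, surface$knots_v)
  W <- surface$weights
  wsum <- Bu %*% W %*% t(Bv)
  out <- array(0, c(length(u), length(v), 3))
  for (c3 in 1:3)
    out[, , c3] <- (Bu %*% (W * surface$control[, , c3]) %*% t(Bv)) / wsum
  out
}

# Surface point and partial derivatives up to second order at (u, v).
# Returns list(S, Su, Sv, Suu, Svv, Suv) as 3-vectors, by the rational
# quotient rule applied to the weighted numerator A and denominator w.
surface_ders <- function(surface, u, v) {
  p <- surface$degrees[1]; q <- surface$degrees[2]
  su <- find_span(u, surface$knots_u)
  sv <- find_span(v, surface$knots_v)
  Du <- ders_basis_funs(su, u, surface$knots_u, 2L)
  Dv <- ders_basis_funs(sv, v, surface$knots_v, 2L)
  iu <- (su - p + 1L):(su + 1L)
  iv <- (sv - q + 1L):(sv + 1L)
  W <- surface$weights[iu, iv, drop = FALSE]
  P <- surface$control[iu, iv, , drop = FALSE]
  # pad derivative rows when degree < 2 (higher derivatives vanish)
  row_or_zero <- function(D, k, len)
    if (k + 1 <= nrow(D)) D[k + 1, ] else numeric(len)
  Nu <- lapply(0:2, row_or_zero, D = Du, len = p + 1)
  Nv <- lapply(0:2, row_or_zero, D = Dv, len = q + 1)
  Amat <- function(ku, kv) {
    blend <- (Nu[[ku + 1]] %o% Nv[[kv + 1]]) * W
    c(sum(blend * P[, , 1]), sum(blend * P[, , 2]), sum(blend * P[, , 3]))
  }
  wval <- function(ku, kv) sum((Nu[[ku + 1]] %o% Nv[[kv + 1]]) * W)
  w <- wval(0, 0)
  S <- Amat(0, 0) / w
  wu <- wval(1, 0); wv <- wval(0, 1)
  Su <- (Amat(1, 0) - wu * S) / w
  Sv <- (Amat(0, 1) - wv * S) / w
  wuu <- wval(2, 0); wvv <- wval(0, 2); wuv <- wval(1, 1)
  Suu <- (Amat(2, 0) - 2 * wu * Su - wuu * S) / w
  Svv <- (Amat(0, 2) - 2 * wv * Sv - wvv * S) / w
  Suv <- (Amat(1, 1) - wu * Sv - wv * Su - wuv * S) / w
  list(S = S, Su = Su, Sv = Sv, Suu = Suu, Svv = Svv, Suv = Suv)
}

## ---- serialization -----------------------------------------------------

#' Write a surface to JSON
#'
#' Stores degrees, knot vectors, the control net (row-major, u-index major)
#' and the weight matrix.
#'
#' @param surface a `spline_surface`.
#' @param path output file path.
#' @export
write_surface_json <- function(surface, path) {
  obj <- list(
    degrees = surface$degrees,
    knots_u = as.numeric(surface$knots_u),
    knots_v = as.numeric(surface$knots_v),
    n_ctrl = dim(surface$control)[1:2],
    control = apply(surface$control, 3, as.numeric),  # u-index major columns
    weights = as.numeric(surface$weights))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a surface from JSON written by [write_surface_json()]
#'
#' @param path JSON file path.
#' @return a `spline_surface`.
#' @export
read_surface_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nu <- obj$n_ctrl[1]; nv <- obj$n_ctrl[2]
  ctrl <- array(as.numeric(obj$control), c(nu, nv, 3))
  ku <- structure(obj$knots_u, degree = as.integer(obj$degrees[1]),
                  class = "knot_vector")
  kvv <- structure(obj$knots_v, degree = as.integer(obj$degrees[2]),
                   class = "knot_vector")
  spline_surface(obj$degrees, ku, kvv, ctrl,
                 matrix(obj$weights, nu, nv))
}

#' Export a triangulated sample of a surface as Wavefront OBJ
#'
#' @param surface a `spline_surface`.
#' @param path output file path.
#' @param n_u,n_v sampling density in each direction.
#' @export
write_surface_obj <- function(surface, path, n_u = 40, n_v = 80) {
  u <- seq(0, 1, length.out = n_u)
  v <- seq(0, 1, length.out = n_v)
  G <- evaluate_surface_grid(surface, u, v)
  vid <- function(i, j) (j - 1L) * n_u + i
  con <- file(path, "w"); on.exit(close(con))
  for (j in seq_len(n_v)) for (i in seq_len(n_u))
    cat(sprintf("v %.9g %.9g %.9g\n", G[i, j, 1], G[i, j, 2], G[i, j, 3]),
        file = con)
  for (j in seq_len(n_v - 1)) for (i in seq_len(n_u - 1)) {
    cat(sprintf("f %d %d %d\n", vid(i, j), vid(i + 1, j), vid(i + 1, j + 1)),
        file = con)
    cat(sprintf("f %d %d %d\n", vid(i, j), vid(i + 1, j + 1), vid(i, j + 1)),
        file = con)
  }
  invisible(path)
}
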