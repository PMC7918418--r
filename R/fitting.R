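#' Surface fitting configuration
#'
#' @param degrees integer pair (p, q): degrees across slices (u) and along
#'   the leaf axis (v).
#' @param n_ctrl integer pair: control-point counts in u and v. Ignored in
#'   `"interpolate"` mode, where the grid dimensions are used.
#' @param parameterization method for [parameterize()].
#' @param mode `"algorithm1"` (per-column/per-row fits with averaged knot
#'   vectors; works for ordered and unordered PSFs), `"interpolate"` or
#'   `"approximate"` (shared-parameter grid algorithms; ordered PSFs only).
#' @return a `fit_config` list.
#' @export
fit_config <- function(degrees = c(2, 2), n_ctrl = c(5, 5),
                       parameterization = "chord_length",
                       mode = c("algorithm1", "interpolate", "approximate")) {
  mode <- match.arg(mode)
  stopifnot(length(degrees) == 2, length(n_ctrl) == 2)
  if (any(n_ctrl < degrees + 1))
    stop("n_ctrl must be at least degree + 1 in each direction")
  structure(list(degrees = as.integer(degrees),
                 n_ctrl = as.integer(n_ctrl),
                 parameterization = parameterization, mode = mode),
            class = "fit_config")
}

# parameterize without user-facing warnings (degenerate columns expected
# for the collapsed tip)
params_safe <- function(points, method) {
  suppressWarnings(parameterize(points, method))
}

#' Fit an ordered PSF with the shared-parameter grid algorithms
#'
#' Classic global tensor-product fitting: one parameter vector and one knot
#' vector per direction (column parameters averaged across columns, row
#' parameters across rows), then curve fits through every column of the
#' grid followed by curve fits through every row of the intermediate
#' control points. `"interpolate"` mode passes through every grid point;
#' `"approximate"` mode solves the endpoint-constrained least-squares
#' problem with `config$n_ctrl` control points.
#'
#' @param psf an ordered `psf`.
#' @param config a `fit_config` with mode `"interpolate"` or
#'   `"approximate"`.
#' @return a `spline_surface` (all weights 1).
#' @export
fit_surface_grid <- function(psf, config) {
  if (!psf$ordered) stop("the grid algorithms require an ordered PSF")
  cols <- psf$columns
  k1 <- nrow(cols[[1]]); l1 <- length(cols)
  p <- config$degrees[1]; q <- config$degrees[2]
  mode <- if (config$mode == "algorithm1") "interpolate" else config$mode
  # common parameters: average per-column (per-row) parameterizations
  ubar <- rowMeans(vapply(cols, params_safe, numeric(k1),
                          method = config$parameterization))
  rows <- lapply(seq_len(k1), function(i)
    do.call(rbind, lapply(cols, function(cc) cc[i, ])))
  vbar <- rowMeans(vapply(rows, params_safe, numeric(l1),
                          method = config$parameterization))
  if (mode == "interpolate") {
    nu <- k1; nv <- l1
  } else {
    nu <- config$n_ctrl[1]; nv <- config$n_ctrl[2]
    if (nu > k1 || nv > l1)
      stop("n_ctrl exceeds the PSF grid dimensions")
  }
  ku <- knots_from_params(ubar, p, nu)
  kv <- knots_from_params(vbar, q, nv)
  fit_dir <- function(points, degree, knots, params) {
    # shared-knot curve fit: square solve (interpolation) or constrained LSQ
    n <- n_basis(knots)
    B <- basis_matrix(params, knots)
    if (n == nrow(points)) return(solve(B, points))
    r <- nrow(points) - 1L
    ctrl <- matrix(0, n, 3)
    ctrl[1, ] <- points[1, ]; ctrl[n, ] <- points[r + 1, ]
    if (n > 2) {
      rhs <- points[2:r, , drop = FALSE] -
        outer(B[2:r, 1], points[1, ]) - outer(B[2:r, n], points[r + 1, ])
      ctrl[2:(n - 1), ] <- qr.coef(qr(B[2:r, 2:(n - 1), drop = FALSE]), rhs)
    }
    ctrl
  }
  R <- array(0, c(nu, l1, 3))
  for (j in seq_len(l1)) R[, j, ] <- fit_dir(cols[[j]], p, ku, ubar)
  ctrl <- array(0, c(nu, nv, 3))
  for (i in seq_len(nu)) ctrl[i, , ] <- fit_dir(R[i, , ], q, kv, vbar)
  spline_surface(c(p, q), ku, kv, ctrl)
}

#' Fit a PSF with per-column/per-row fits and averaged knot vectors
#'
#' The fitting algorithm that also handles unordered PSFs: each column is
#' approximated independently with its own parameters and knot vector
#' (`n_ctrl[1]` control points, degree p), the direction's knot vector is
#' the element-wise mean of the per-column knot vectors; the rows of the
#' intermediate control net are then fitted the same way in v
#' (`n_ctrl[2]` control points, degree q) and the v knot vector is the
#' element-wise mean of the per-row ones. Means of equal-length clamped
#' non-decreasing knot vectors are again clamped and non-decreasing.
#'
#' @param psf an ordered or unordered `psf`; every column must hold at
#'   least `n_ctrl[1]` points.
#' @param config a `fit_config`.
#' @return a `spline_surface` (all weights 1).
#' @export
fit_surface_algorithm1 <- function(psf, config) {
  cols <- psf$columns
  l1 <- length(cols)
  p <- config$degrees[1]; q <- config$degrees[2]
  nu <- config$n_ctrl[1]; nv <- config$n_ctrl[2]
  if (nv > l1) stop("n_ctrl[2] exceeds the number of PSF columns")
  short <- which(vapply(cols, nrow, 0L) < nu)
  if (length(short))
    stop("PSF column(s) ", paste(short, collapse = ", "),
         " hold fewer than n_ctrl[1] = ", nu, " points")
  # duplicate nearest-neighbour snaps are documented for ordered columns;
  # the zero-chord warning is expected here, not actionable by the caller
  quiet_fit <- function(points, degree, n_ctrl) {
    withCallingHandlers(
      fit_curve_approximate(points, degree, n_ctrl,
                            parameterization = config$parameterization),
      warning = function(w) {
        if (grepl("coincident|coincide", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  cfits <- lapply(cols, quiet_fit, degree = p, n_ctrl = nu)
  ku_mean <- rowMeans(vapply(cfits, function(cv) as.numeric(cv$knots),
                             numeric(nu + p + 1)))
  ku <- structure(ku_mean, degree = as.integer(p), class = "knot_vector")
  R <- array(0, c(nu, l1, 3))
  for (j in seq_len(l1)) R[, j, ] <- cfits[[j]]$control
  rfits <- lapply(seq_len(nu), function(i)
    fit_curve_approximate(R[i, , ], degree = q, n_ctrl = nv,
                          parameterization = config$parameterization))
  kv_mean <- rowMeans(vapply(rfits, function(cv) as.numeric(cv$knots),
                             numeric(nv + q + 1)))
  kv <- structure(kv_mean, degree = as.integer(q), class = "knot_vector")
  ctrl <- array(0, c(nu, nv, 3))
  for (i in seq_len(nu)) ctrl[i, , ] <- rfits[[i]]$control
  spline_surface(c(p, q), ku, kv, ctrl)
}
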