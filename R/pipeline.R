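#' Fit a parametric leaf surface to a point cloud
#'
#' The full modelling pipeline: PCA pose standardization, slicing along the
#' leaf axis, slice selection, point-set-to-be-fitted (PSF) extraction,
#' B-spline surface fitting, accuracy evaluation on an independent test
#' subset, and (optionally) conversion to NURBS form by particle-swarm
#' weight optimization. Defaults reproduce the case-study configuration:
#' 50 interior slices, 7 selected, 7 points per ordered column
#' (tl = tr = 2), a degree (2,2) surface with a 5 x 5 control net, F =
#' 0.8 RMSE + 0.2 MV, and a 90-point test subset (10 columns x 9 points).
#'
#' @param cloud a `point_cloud`, `slpc`, n x 3 matrix, or a file path
#'   readable by [read_point_cloud()].
#' @param nums number of interior slices (default 50).
#' @param n_selected number of selected slices including base and tip
#'   (default 7).
#' @param tl,tr intermediate feature points per side (default 2).
#' @param psf `"unordered"` (default) or `"ordered"` PSF construction.
#' @param config a [fit_config()]; its mode chooses the fitting algorithm
#'   (`"algorithm1"` works for both PSF kinds; the grid modes need
#'   `psf = "ordered"`).
#' @param alpha1,alpha2 error-metric weights (defaults 0.8, 0.2).
#' @param test_subset length-2 integer vector: test columns and points per
#'   column (default `c(10, 9)`, i.e. 90 points).
#' @param pso `NULL` to keep the B-spline fit, or a [pso_config()] to
#'   optimize control-point weights into NURBS form.
#' @param quiet suppress per-stage progress messages (default TRUE).
#' @return an object of class `leaf_fit` with components `slpc`, `slices`
#'   (selected), `psf`, `surface` (the B-spline fit), `report` (its
#'   `fit_report`), and when PSO ran also `nurbs`, `nurbs_report`, `trace`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `residuals`,
#'   `fitted`, `plot`.
#' @examples
#' leaf <- generate_leaf(leaf_spec(length = 60, n_points = 5000, seed = 7))
#' fit <- fit_leaf_surface(leaf$cloud, nums = 20)
#' fit
#' head(residuals(fit))
#' predict(fit, u = c(0.5, 0.5), v = c(0.25, 0.75))
#' @export
fit_leaf_surface <- function(cloud, nums = 50, n_selected = 7,
                             tl = 2, tr = 2,
                             psf = c("unordered", "ordered"),
                             config = fit_config(),
                             alpha1 = 0.8, alpha2 = 0.2,
                             test_subset = c(10, 9),
                             pso = NULL, quiet = TRUE) {
  psf <- match.arg(psf)
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.character(cloud)) cloud <- read_point_cloud(cloud)
  t0 <- proc.time()[3]
  slpc <- if (inherits(cloud, "slpc")) cloud else pca_normalize(cloud)
  say("pose: %d points standardized, leaf length %.2f mm",
      nrow(slpc$points), slpc$L)
  slices <- slice_cloud(slpc, nums)
  selected <- select_slices(slices, n_selected)
  say("slicing: %d interior slices (Ws %.3f mm), %d selected",
      nums, attr(slices, "Ws"), n_selected)
  ps <- if (psf == "ordered") build_ordered_psf(slpc, selected, tl, tr)
        else build_unordered_psf(slpc, selected, tl, tr)
  say("psf: %s, %d points", psf, nrow(psf_points(ps)))
  surface <- if (config$mode == "algorithm1") fit_surface_algorithm1(ps, config)
             else fit_surface_grid(ps, config)
  say("fit: degree (%d,%d), %d x %d control net", config$degrees[1],
      config$degrees[2], dim(surface$control)[1], dim(surface$control)[2])
  subset <- build_test_subset(slpc, test_subset[1], test_subset[2])
  report <- evaluate_fit(surface, subset, alpha1, alpha2, config = config)
  say("evaluate: RMSE %.4f mm, MV %.4f mm over %d points",
      report$rmse, report$mv, report$n)
  out <- list(slpc = slpc, slices = selected, psf = ps,
              surface = surface, report = report, subset = subset,
              config = config, alpha = c(alpha1, alpha2),
              call = match.call())
  if (!is.null(pso)) {
    opt <- optimize_weights(surface, subset, alpha1, alpha2, pso)
    out$nurbs <- opt$surface
    out$nurbs_report <- opt$report
    out$trace <- opt$trace
    say("pso: F %.4f -> %.4f", opt$trace$initial_f, min(opt$trace$best_f))
  }
  out$elapsed <- proc.time()[3] - t0
  class(out) <- "leaf_fit"
  out
}

#' Final surface and report of a leaf fit
#'
#' The NURBS surface/report when PSO weight optimization ran, otherwise the
#' B-spline ones.
#'
#' @param fit a `leaf_fit`.
#' @return `final_surface()`: a `spline_surface`; `final_report()`: a
#'   `fit_report`.
#' @export
final_surface <- function(fit) fit$nurbs %||% fit$surface

#' @rdname final_surface
#' @export
final_report <- function(fit) fit$nurbs_report %||% fit$report

#' @export
print.leaf_fit <- function(x, ...) {
  s <- final_surface(x); r <- final_report(x)
  cat(sprintf(
    "Leaf surface fit: %s degree (%d,%d), %d x %d control net\n",
    if (is_rational(s)) "NURBS" else "B-spline",
    s$degrees[1], s$degrees[2], dim(s$control)[1], dim(s$control)[2]))
  cat(sprintf("  leaf length %.2f mm, %d cloud points, %d PSF points\n",
              x$slpc$L, nrow(x$slpc$points), nrow(psf_points(x$psf))))
  cat(sprintf("  RMSE %.4f mm, MV %.4f mm, F %.4f mm (%d test points)\n",
              r$rmse, r$mv, r$f_value, r$n))
  invisible(x)
}

#' @export
summary.leaf_fit <- function(object, ...) {
  x <- object
  cat("Call: "); print(x$call)
  print(x)
  cat(sprintf("  PSF: %s, column sizes %s\n",
              if (x$psf$ordered) "ordered" else "unordered",
              paste(vapply(x$psf$columns, nrow, 0L), collapse = ",")))
  cat(sprintf("  parameterization: %s, mode: %s\n",
              x$config$parameterization, x$config$mode))
  if (!is.null(x$trace))
    cat(sprintf("  PSO: F %.4f -> %.4f (B-spline RMSE %.4f, NURBS RMSE %.4f)\n",
                x$trace$initial_f, min(x$trace$best_f),
                x$report$rmse, x$nurbs_report$rmse))
  q <- stats::quantile(final_report(x)$distances, c(0.5, 0.9, 1))
  cat(sprintf("  test distances: median %.4f, 90%% %.4f, max %.4f mm\n",
              q[1], q[2], q[3]))
  invisible(x)
}

#' @export
coef.leaf_fit <- function(object, ...) {
  s <- final_surface(object)
  structure(s$control, weights = s$weights)
}

#' Evaluate a fitted leaf surface
#'
#' @param object a `leaf_fit`.
#' @param u,v parameter vectors in [0, 1] (default a 20 x 20 grid spread).
#' @param ... unused.
#' @return matrix of surface points (mm).
#' @export
predict.leaf_fit <- function(object, u = NULL, v = NULL, ...) {
  s <- final_surface(object)
  if (is.null(u) || is.null(v)) {
    g <- expand.grid(u = seq(0, 1, length.out = 20),
                     v = seq(0, 1, length.out = 20))
    u <- g$u; v <- g$v
  }
  out <- evaluate_surface(s, u, v)
  colnames(out) <- c("x", "y", "z")
  out
}

#' @export
residuals.leaf_fit <- function(object, ...) final_report(object)$distances

#' @export
fitted.leaf_fit <- function(object, ...) {
  s <- final_surface(object)
  pts <- psf_points(object$subset)
  t(vapply(seq_len(nrow(pts)), function(i)
    project_point(s, pts[i, ])$foot_point, numeric(3)))
}

#' Diagnostic plot of a fitted leaf surface
#'
#' Two panels: the planform (x-y) of the standardized cloud with the fitted
#' surface boundary, and cross-section profiles (y-z) at several stations
#' along the leaf with the corresponding surface curves.
#'
#' @param x a `leaf_fit`.
#' @param stations v-parameters of the plotted cross sections.
#' @param ... passed to `plot`.
#' @export
plot.leaf_fit <- function(x, stations = c(0.2, 0.5, 0.8), ...) {
  s <- final_surface(x)
  P <- x$slpc$points
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  idx <- seq(1, nrow(P), length.out = min(4000, nrow(P)))
  graphics::plot(P[idx, 1], P[idx, 2], pch = ".", col = "grey60",
                 xlab = "x (mm)", ylab = "y (mm)", main = "planform",
                 asp = 1, ...)
  for (ub in c(0, 1)) {
    b <- evaluate_surface(s, rep(ub, 100), seq(0, 1, length.out = 100))
    graphics::lines(b[, 1], b[, 2], col = "red3", lwd = 2)
  }
  graphics::plot(NULL, xlim = range(P[, 2]), ylim = range(P[, 3]),
                 xlab = "y (mm)", ylab = "z (mm)", main = "cross sections")
  cols <- grDevices::hcl.colors(length(stations), "Dark 3")
  L <- x$slpc$L; xmin <- min(P[, 1])
  for (k in seq_along(stations)) {
    cs <- evaluate_surface(s, seq(0, 1, length.out = 100), stations[k])
    near <- abs(P[, 1] - (xmin + stations[k] * L)) < L / 60
    graphics::points(P[near, 2], P[near, 3], pch = ".", col = "grey60")
    graphics::lines(cs[, 2], cs[, 3], col = cols[k], lwd = 2)
  }
  invisible(x)
}

#' Downsampling accuracy experiment
#'
#' Voxel-grid downsamples each cloud to a series of target sizes (with
#' randomized grid origins across repeats), refits each downsampled cloud
#' with the reduced configuration (10 interior slices, 8 selected, degree
#' (2,2), 3 x 7 control net, unordered PSF), and reports the mean RMSE and
#' mean MV per (cloud, target) cell over the repeats.
#'
#' @param clouds list of `point_cloud`s (or objects coercible by
#'   [cloud_points()]).
#' @param targets downsampling targets (default the 300 .. 32,000 series).
#' @param repeats repetitions per cell (default 10).
#' @param seed integer seed for the randomized voxel origins.
#' @param config fitting configuration (default the reduced 3 x 7 net).
#' @param nums,n_selected slicing configuration (defaults 10 and 8).
#' @param quiet suppress progress messages.
#' @return data frame with columns `cloud`, `target`, `mean_rmse`,
#'   `mean_mv` (one row per cloud x target cell).
#' @export
run_downsample_experiment <- function(clouds,
                                      targets = c(300, 500, 1000, 2000,
                                                  4000, 8000, 16000, 32000),
                                      repeats = 10, seed = 1,
                                      config = fit_config(degrees = c(2, 2),
                                                          n_ctrl = c(3, 7)),
                                      nums = 10, n_selected = 8,
                                      quiet = TRUE) {
  if (!length(clouds)) stop("need at least one cloud")
  rows <- list()
  with_seed(seed, {
    for (ci in seq_along(clouds)) {
      P <- cloud_points(clouds[[ci]])
      for (tg in targets) {
        rmses <- mvs <- numeric(repeats)
        for (rep_i in seq_len(repeats)) {
          dc <- voxel_downsample(P, min(tg, nrow(P)),
                                 origin_jitter = stats::runif(3))
          fit <- fit_leaf_surface(dc, nums = nums,
                                  n_selected = n_selected,
                                  psf = "unordered", config = config,
                                  quiet = TRUE)
          rmses[rep_i] <- fit$report$rmse
          mvs[rep_i] <- fit$report$mv
        }
        if (!quiet)
          message(sprintf("cloud %d target %d: mean RMSE %.3f, mean MV %.3f",
                          ci, tg, mean(rmses), mean(mvs)))
        rows[[length(rows) + 1L]] <-
          data.frame(cloud = ci, target = tg,
                     mean_rmse = mean(rmses), mean_mv = mean(mvs))
      }
    }
  })
  do.call(rbind, rows)
}
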