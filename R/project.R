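#' Euclidean distance from a point to a spline surface
#'
#' Point inversion by Newton iteration on the squared-distance objective.
#' The primary starting parameters follow the leaf geometry: with the leaf
#' axis in the v direction,
#' \deqn{u_1 = \frac{\|G - S(0, 0.5)\|}{\|G - S(0, 0.5)\| + \|S(1, 0.5) - G\|}}
#' and v1 analogously between S(u1, 0) and S(u1, 1). Because this ratio
#' start can land in a stationary point of the distance field (e.g. for
#' edge points near the collapsed tip), a second Newton run is seeded from
#' the best cell of a coarse parameter grid and the closer of the two
#' results is returned. Newton steps use the analytic first and second
#' surface derivatives; parameters are clamped to [0, 1]; a step that
#' increases the squared distance is halved (up to 20 times); iteration
#' stops when the parameter step norm falls below 1e-10 or after 100
#' iterations.
#'
#' @param surface a `spline_surface`.
#' @param G query point (length-3 numeric).
#' @param coarse_n coarse seeding grid resolution per direction
#'   (default 32).
#' @return a `projection_result` list: `u`, `v`, `foot_point`, `distance`
#'   (mm), `iterations`, `converged`. Non-convergence returns the best
#'   iterate with `converged = FALSE`, never an error.
#' @export
project_point <- function(surface, G, coarse_n = 32) {
  G <- as.numeric(G)
  starts <- rbind(ratio_init(surface, G),
                  coarse_seed(surface, G, coarse_n))
  runs <- lapply(seq_len(nrow(starts)), function(k)
    newton_invert(surface, G, starts[k, 1], starts[k, 2]))
  best <- runs[[which.min(vapply(runs, `[[`, 0, "f"))]]
  foot <- as.numeric(evaluate_surface(surface, best$u, best$v))
  structure(list(u = best$u, v = best$v, foot_point = foot,
                 distance = sqrt(best$f),
                 iterations = sum(vapply(runs, `[[`, 0L, "iter")),
                 converged = best$converged || sqrt(best$f) < 1e-10),
            class = "projection_result")
}

# ratio initialization between opposite boundary midpoints
ratio_init <- function(surface, G) {
  a <- sqrt(sum((G - evaluate_surface(surface, 0, 0.5))^2))
  b <- sqrt(sum((evaluate_surface(surface, 1, 0.5) - G)^2))
  u <- if (a + b > 0) a / (a + b) else 0.5
  a <- sqrt(sum((G - evaluate_surface(surface, u, 0))^2))
  b <- sqrt(sum((evaluate_surface(surface, u, 1) - G)^2))
  v <- if (a + b > 0) a / (a + b) else 0.5
  c(u, v)
}

# best cells of an n x n parameter grid (grid points reusable via
# precomputed evaluate_surface_grid array); returns the k best cells so
# Newton can be multi-started — a single start is unreliable when the
# query sits near the boundary of two distance basins
coarse_seed <- function(surface, G, n = 32, grid = NULL, uv = NULL, k = 4) {
  if (is.null(grid)) {
    uv <- seq(0, 1, length.out = n)
    grid <- evaluate_surface_grid(surface, uv, uv)
  }
  d2 <- (grid[, , 1] - G[1])^2 + (grid[, , 2] - G[2])^2 +
    (grid[, , 3] - G[3])^2
  ord <- order(d2)[seq_len(min(k, length(d2)))]
  ij <- arrayInd(ord, dim(d2))
  cbind(uv[ij[, 1]], uv[ij[, 2]])
}

# damped, clamped Newton iteration on the squared distance
newton_invert <- function(surface, G, u, v) {
  d2 <- function(uv) {
    s <- evaluate_surface(surface, uv[1], uv[2])
    sum((G - s)^2)
  }
  f <- d2(c(u, v))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(100L)) {
    dd <- surface_ders(surface, u, v)
    r <- dd$S - G
    g <- c(sum(r * dd$Su), sum(r * dd$Sv))
    H <- matrix(c(sum(dd$Su^2) + sum(r * dd$Suu),
                  sum(dd$Su * dd$Sv) + sum(r * dd$Suv),
                  sum(dd$Su * dd$Sv) + sum(r * dd$Suv),
                  sum(dd$Sv^2) + sum(r * dd$Svv)), 2, 2)
    # active-set reduction: a parameter clamped at its bound whose gradient
    # pushes outward is frozen, leaving a 1-D Newton step in the other
    act_u <- (u <= 0 && g[1] > 0) || (u >= 1 && g[1] < 0)
    act_v <- (v <= 0 && g[2] > 0) || (v >= 1 && g[2] < 0)
    if (act_u && act_v) { converged <- TRUE; break }
    if (act_u) {
      step <- c(0, if (H[2, 2] > 0) -g[2] / H[2, 2] else -g[2])
    } else if (act_v) {
      step <- c(if (H[1, 1] > 0) -g[1] / H[1, 1] else -g[1], 0)
    } else {
      step <- tryCatch(-solve(H, g), error = function(e) -g)
    }
    if (!all(is.finite(step))) step <- -g
    accepted <- FALSE
    for (h in 0:20) {
      uv_new <- pmin(pmax(c(u, v) + step / 2^h, 0), 1)
      f_new <- d2(uv_new)
      if (f_new <= f) {
        moved <- sqrt(sum((uv_new - c(u, v))^2))
        u <- uv_new[1]; v <- uv_new[2]; f <- f_new
        accepted <- TRUE
        if (moved < 1e-10) converged <- TRUE
        break
      }
    }
    if (!accepted || converged) {
      if (!accepted) {
        gp <- c(if (act_u) 0 else g[1], if (act_v) 0 else g[2])
        if (max(abs(gp)) < 1e-8) converged <- TRUE
      }
      break
    }
  }
  list(u = u, v = v, f = f, iter = iter, converged = converged)
}

#' Point-to-surface distances for a set of points
#'
#' Batched [project_point()]: the coarse seeding grid is evaluated once and
#' shared across all queries.
#'
#' @param surface a `spline_surface`.
#' @param points n x 3 matrix.
#' @param coarse_n coarse seeding grid resolution (default 32).
#' @return numeric vector of distances (mm).
#' @export
surface_distances <- function(surface, points, coarse_n = 32) {
  points <- as_xyz(points)
  uv <- seq(0, 1, length.out = coarse_n)
  grid <- evaluate_surface_grid(surface, uv, uv)
  vapply(seq_len(nrow(points)), function(i) {
    G <- points[i, ]
    starts <- rbind(ratio_init(surface, G),
                    coarse_seed(surface, G, grid = grid, uv = uv))
    f <- vapply(seq_len(nrow(starts)), function(s)
      newton_invert(surface, G, starts[s, 1], starts[s, 2])$f, numeric(1))
    sqrt(min(f))
  }, numeric(1))
}

#' Accuracy report for a fitted surface
#'
#' Projects every test point onto the surface and reports the
#' root-mean-square error \eqn{RMSE = \sqrt{\sum d_i^2 / n}}, the maximum
#' distance MV, and the weighted metric \eqn{F = \alpha_1 RMSE + \alpha_2
#' MV} with \eqn{\alpha_1 + \alpha_2 = 1}.
#'
#' @param surface a `spline_surface`.
#' @param subset an ordered `psf` (the evaluation subset) or an n x 3
#'   matrix of test points.
#' @param alpha1,alpha2 non-negative weights summing to 1 (defaults 0.8 and
#'   0.2).
#' @param config optional `fit_config` echoed into the report.
#' @return a `fit_report` list: `rmse`, `mv`, `f_value`, `alpha1`,
#'   `alpha2`, `distances`, `n`, `config`.
#' @export
evaluate_fit <- function(surface, subset, alpha1 = 0.8, alpha2 = 0.2,
                         config = NULL) {
  if (alpha1 < 0 || alpha2 < 0 || abs(alpha1 + alpha2 - 1) > 1e-12)
    stop("alpha1 and alpha2 must be non-negative and sum to 1")
  pts <- if (inherits(subset, "psf")) psf_points(subset) else as_xyz(subset)
  if (nrow(pts) == 0) stop("empty evaluation subset")
  d <- surface_distances(surface, pts)
  rmse <- sqrt(mean(d^2))
  mv <- max(d)
  structure(list(rmse = rmse, mv = mv,
                 f_value = alpha1 * rmse + alpha2 * mv,
                 alpha1 = alpha1, alpha2 = alpha2,
                 distances = d, n = length(d), config = config),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf(
    "Fit accuracy over %d test points: RMSE %.4f mm, MV %.4f mm, F %.4f mm (a1=%.2f, a2=%.2f)\n",
    x$n, x$rmse, x$mv, x$f_value, x$alpha1, x$alpha2))
  invisible(x)
}

#' Write a fit report to JSON
#'
#' @param report a `fit_report`.
#' @param path output file.
#' @export
write_fit_report <- function(report, path) {
  jsonlite::write_json(report[c("rmse", "mv", "f_value", "alpha1",
                                "alpha2", "n", "distances")],
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
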