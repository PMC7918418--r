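#' Particle swarm configuration for NURBS weight optimization
#'
#' @param n_particles swarm size N (default 5, the case-study value).
#' @param max_iter iteration count jmax (default 10).
#' @param c1,c2 cognitive and social learning rates (default 2).
#' @param theta_max,theta_min inertia-weight bounds for the linear decrease
#'   (defaults 0.9 and 0.4).
#' @param weight_bounds positive search interval for every control-point
#'   weight (default c(0.1, 10)); positions are clipped to it, keeping the
#'   rational denominator positive.
#' @param seed integer RNG seed; `NULL` uses the current RNG stream.
#' @return a `pso_config` list.
#' @export
pso_config <- function(n_particles = 5, max_iter = 10, c1 = 2, c2 = 2,
                       theta_max = 0.9, theta_min = 0.4,
                       weight_bounds = c(0.1, 10), seed = NULL) {
  if (weight_bounds[1] <= 0 || weight_bounds[2] <= weight_bounds[1])
    stop("weight_bounds must be an increasing positive interval")
  if (n_particles < 2) stop("need at least 2 particles")
  structure(list(n_particles = as.integer(n_particles),
                 max_iter = as.integer(max_iter), c1 = c1, c2 = c2,
                 theta_max = theta_max, theta_min = theta_min,
                 weight_bounds = weight_bounds, seed = seed),
            class = "pso_config")
}

#' Linearly decreasing inertia weight
#'
#' \eqn{\theta = \theta_{max} - (\theta_{max} - \theta_{min}) j / j_{max}}:
#' strong global search early, local search late.
#'
#' @param j current iteration, 0 <= j <= jmax.
#' @param config a `pso_config`.
#' @return inertia weight for iteration `j`.
#' @export
inertia <- function(j, config) {
  if (j < 0 || j > config$max_iter) stop("iteration out of range")
  config$theta_max - (config$theta_max - config$theta_min) * j / config$max_iter
}

#' Optimize NURBS control-point weights by particle swarm
#'
#' Searches the flattened weight matrix (one dimension per control point)
#' to minimize \eqn{F(X) = \alpha_1 RMSE + \alpha_2 MV} of the test subset
#' against the re-weighted surface. One particle starts at the all-ones
#' weight matrix (the B-spline solution), so the optimized F never exceeds
#' the unweighted F; the rest start uniformly inside `weight_bounds`.
#' Velocity updates use fresh uniform r1, r2 per dimension per step and a
#' global-best topology; positions are clipped to the bounds.
#'
#' @param surface a `spline_surface` (its control net and knots are kept
#'   fixed; only weights change).
#' @param subset evaluation subset (ordered `psf` or n x 3 matrix).
#' @param alpha1,alpha2 metric weights (sum to 1).
#' @param config a `pso_config`.
#' @return list with `surface` (NURBS with the best weights), `report`
#'   (its `fit_report`) and `trace` (an `optimization_trace`: per-iteration
#'   best F, the initial F, and the final weight matrix).
#' @export
optimize_weights <- function(surface, subset, alpha1 = 0.8, alpha2 = 0.2,
                             config = pso_config()) {
  nu <- dim(surface$control)[1]; nv <- dim(surface$control)[2]
  d <- nu * nv
  lo <- config$weight_bounds[1]; hi <- config$weight_bounds[2]
  pts <- if (inherits(subset, "psf")) psf_points(subset) else as_xyz(subset)
  fobj <- function(x) {
    s2 <- surface; s2$weights <- matrix(x, nu, nv)
    r <- evaluate_fit(s2, pts, alpha1, alpha2)
    r$f_value
  }
  N <- config$n_particles
  with_seed(config$seed, {
    X <- matrix(stats::runif(N * d, lo, hi), N, d)
    X[1, ] <- 1                      # the B-spline solution
    V <- matrix(stats::runif(N * d, -(hi - lo) / 10, (hi - lo) / 10), N, d)
    vmax <- (hi - lo) / 2
    f <- apply(X, 1, fobj)
    pbest <- X; pbest_f <- f
    gi <- which.min(f)
    gbest <- X[gi, ]; gbest_f <- f[gi]
    f0 <- f[1]                       # all-ones particle = unweighted fit
    best_trace <- numeric(config$max_iter)
    for (j in seq_len(config$max_iter)) {
      th <- inertia(j, config)
      r1 <- matrix(stats::runif(N * d), N, d)
      r2 <- matrix(stats::runif(N * d), N, d)
      V <- th * V + config$c1 * r1 * (pbest - X) +
        config$c2 * r2 * (matrix(gbest, N, d, byrow = TRUE) - X)
      V <- pmin(pmax(V, -vmax), vmax)
      X <- pmin(pmax(X + V, lo), hi)
      f <- apply(X, 1, fobj)
      imp <- f < pbest_f
      pbest[imp, ] <- X[imp, ]; pbest_f[imp] <- f[imp]
      if (min(pbest_f) < gbest_f) {
        gi <- which.min(pbest_f)
        gbest <- pbest[gi, ]; gbest_f <- pbest_f[gi]
      }
      best_trace[j] <- gbest_f
    }
  })
  out <- surface
  out$weights <- matrix(gbest, nu, nv)
  report <- evaluate_fit(out, pts, alpha1, alpha2)
  trace <- structure(list(initial_f = f0, best_f = best_trace,
                          weights = out$weights, report = report),
                     class = "optimization_trace")
  list(surface = out, report = report, trace = trace)
}

#' @export
print.optimization_trace <- function(x, ...) {
  cat(sprintf("PSO weight optimization: F %.4f -> %.4f over %d iterations\n",
              x$initial_f, min(x$best_f), length(x$best_f)))
  invisible(x)
}
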