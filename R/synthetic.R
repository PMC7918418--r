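#' Synthetic leaf specification
#'
#' Parameters of the synthetic single-leaf scans used for validation. The
#' defaults mirror handheld-scanner captures of tea leaves: 33,000-50,000
#' points, leaf length 45-85 mm, a smooth convex blade with an optional
#' midrib ridge, a narrow (about 2.5 mm) petiole end, and sub-millimetre
#' measurement noise.
#'
#' @param length leaf length in mm (45-85 typical).
#' @param max_width maximum blade width in mm (default 0.4 * length).
#' @param camber height of the convex blade arch in mm (default
#'   0.08 * length).
#' @param midrib_height extra ridge height along the midrib in mm; 0 gives
#'   a smooth convex blade (default 1).
#' @param wrinkle_amplitude amplitude of a low-frequency surface wrinkle in
#'   mm (default 0).
#' @param n_points number of sampled points (default 40,000).
#' @param noise_sd isotropic Gaussian measurement noise, mm (default 0).
#' @param pose `NULL` for the standard pose, `"random"` for a seeded random
#'   rigid transform, or `list(rotation = 3x3, translation = length-3)`.
#' @param seed integer RNG seed for sampling, noise and random pose.
#' @return a `leaf_spec` list.
#' @export
leaf_spec <- function(length = 60, max_width = 0.4 * length,
                      camber = 0.08 * length, midrib_height = 1,
                      wrinkle_amplitude = 0, n_points = 40000,
                      noise_sd = 0, pose = NULL, seed = 1) {
  stopifnot(length > 0, n_points >= 100, noise_sd >= 0)
  structure(list(length = length, max_width = max_width, camber = camber,
                 midrib_height = midrib_height,
                 wrinkle_amplitude = wrinkle_amplitude,
                 n_points = as.integer(n_points), noise_sd = noise_sd,
                 pose = pose, seed = seed),
            class = "leaf_spec")
}

# ground-truth surface: degree (2,2), 5 x 7 control net, uniform clamped
# knots; u runs across the blade, v base -> tip; the tip column collapses
# to a single point so the degenerate tip path is exercised downstream
leaf_truth_surface <- function(spec) {
  L <- spec$length
  xj <- seq(-L / 2, L / 2, length.out = 7)
  half_w <- c(0.05, 0.55, 0.95, 1, 0.85, 0.5, 0) * spec$max_width / 2
  arch <- c(0.15, 0.8, 1, 1, 0.8, 0.4, 0) * spec$camber
  ridge <- c(0, 0.8, 1, 1, 0.8, 0.4, 0) * spec$midrib_height
  yi <- c(-1, -0.55, 0, 0.55, 1)
  zi <- c(0, 0.8, 1, 0.8, 0)
  ctrl <- array(0, c(5, 7, 3))
  for (j in 1:7) {
    ctrl[, j, 1] <- xj[j]
    ctrl[, j, 2] <- yi * half_w[j]
    ctrl[, j, 3] <- zi * arch[j] + c(0, 0, 1, 0, 0) * ridge[j]
    if (spec$wrinkle_amplitude > 0 && j > 1 && j < 7)
      ctrl[, j, 3] <- ctrl[, j, 3] +
        spec$wrinkle_amplitude * sin(3 * pi * (j - 1) / 6 + seq_len(5))
  }
  ctrl[, 7, 2:3] <- 0                       # coincident tip control points
  ku <- knot_vector(2, c(1, 2) / 3)
  kv <- knot_vector(2, (1:4) / 5)
  spline_surface(c(2, 2), ku, kv, ctrl)
}

# a uniformly random rotation (QR-based, det +1)
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qrm <- qr(M)
  R <- qr.Q(qrm) %*% diag(sign(diag(qr.R(qrm))))
  if (det(R) < 0) R[, 3] <- -R[, 3]
  R
}

#' Generate a synthetic leaf point cloud with known ground truth
#'
#' Samples `n_points` parameter pairs uniformly on the ground-truth surface
#' of the leaf specification, adds isotropic Gaussian noise, and applies the
#' rigid pose transform. Fixed seeds give bit-identical clouds.
#'
#' @param spec a [leaf_spec()].
#' @return list with `cloud` (a `point_cloud` in the posed frame),
#'   `surface` (the ground-truth `spline_surface` in the standard frame),
#'   `pose` (the applied `rotation`/`translation`), and `spec`.
#' @export
generate_leaf <- function(spec = leaf_spec()) {
  truth <- leaf_truth_surface(spec)
  with_seed(spec$seed, {
    u <- stats::runif(spec$n_points)
    v <- stats::runif(spec$n_points)
    P <- evaluate_surface(truth, u, v)
    if (spec$noise_sd > 0)
      P <- P + matrix(stats::rnorm(3 * spec$n_points, 0, spec$noise_sd),
                      ncol = 3)
    pose <- spec$pose
    if (identical(pose, "random"))
      pose <- list(rotation = random_rotation(),
                   translation = stats::runif(3, -100, 100))
    if (!is.null(pose))
      P <- P %*% t(pose$rotation) +
        matrix(pose$translation, nrow(P), 3, byrow = TRUE)
  })
  list(cloud = point_cloud(P, provenance = "synthetic leaf"),
       surface = truth,
       pose = if (is.null(spec$pose)) NULL else pose,
       spec = spec)
}
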