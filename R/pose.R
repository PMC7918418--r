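#' Point cloud container
#'
#' A thin wrapper around an n x 3 coordinate matrix (units mm) with an
#' optional provenance tag.
#'
#' @param points n x 3 numeric matrix or data frame of coordinates.
#' @param provenance free-text source tag.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, provenance = "") {
  structure(list(points = as_xyz(points),
                 provenance = as.character(provenance)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("Point cloud:", nrow(x$points), "points")
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Extract the coordinate matrix of a cloud-like object
#'
#' @param cloud a `point_cloud`, `slpc`, or anything coercible to an n x 3
#'   numeric matrix.
#' @return n x 3 numeric matrix.
#' @export
cloud_points <- function(cloud) {
  if (inherits(cloud, "point_cloud") || inherits(cloud, "slpc"))
    cloud$points else as_xyz(cloud)
}

#' Standardize leaf pose by principal component analysis
#'
#' Centers the cloud at its centroid and rotates it so the first, second and
#' third principal components align with the x, y and z axes (decreasing
#' variance). Sign ambiguities are resolved deterministically: the x axis is
#' oriented so the narrower leaf end (the petiole/base, judged by the
#' y-extent of points within the first 5% of the leaf length at each end)
#' sits at min(x); the z axis so the blade center lies above the blade
#' edges (the convex face bulges towards +z, judged by the quadratic trend
#' of z across the blade width); the y axis completes a right-handed
#' frame.
#'
#' @param cloud a `point_cloud`, `slpc`, or n x 3 matrix.
#' @return an object of class `slpc` (standard leaf point cloud) with fields
#'   `points`, `rotation` (3 x 3, applied as `points_out = (points_in -
#'   centroid) %*% t(rotation)`), `translation` (the centroid), and leaf
#'   length `L = max(x) - min(x)`.
#' @export
pca_normalize <- function(cloud) {
  P <- cloud_points(cloud)
  if (nrow(P) < 4) stop("PCA pose normalization needs at least 4 points")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  cv <- crossprod(Pc) / (nrow(Pc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] < 1e-12 * eg$values[1])
    stop("degenerate (collinear) point cloud: PCA axes undefined")
  R <- t(eg$vectors)           # rows = principal axes, decreasing variance
  X <- Pc %*% t(R)
  # axis-1 sign: narrower end (base) to min(x)
  L <- diff(range(X[, 1]))
  band <- 0.05 * L
  wlo <- diff(range(X[X[, 1] <= min(X[, 1]) + band, 2]))
  whi <- diff(range(X[X[, 1] >= max(X[, 1]) - band, 2]))
  if (wlo > whi) R[1, ] <- -R[1, ]
  # axis-3 sign: the blade is convex towards +z, i.e. the cross-section
  # center sits above the edges. The quadratic coefficient of z against
  # y^2 is negative for a dome opening downwards in y at its edges; flip
  # when it is positive. (A median-vs-midrange rule is not reliable here:
  # the z distribution of a cambered blade can place the median on either
  # side of the midrange.)
  z <- as.numeric(Pc %*% R[3, ])
  y2 <- as.numeric(Pc %*% R[2, ])^2
  D <- cbind(1, y2)
  coef2 <- solve(crossprod(D), crossprod(D, z))[2]
  if (coef2 > 0) R[3, ] <- -R[3, ]
  # right-handed frame
  R[2, ] <- pracma_cross(R[3, ], R[1, ])
  X <- Pc %*% t(R)
  structure(list(points = X, rotation = R, translation = ctr,
                 L = diff(range(X[, 1]))),
            class = "slpc")
}

# 3-vector cross product (kept local; no geometry dependency needed)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.slpc <- function(x, ...) {
  cat(sprintf("Standard leaf point cloud: %d points, length %.2f mm\n",
              nrow(x$points), x$L))
  invisible(x)
}

#' Voxel-grid downsampling
#'
#' Replaces all points falling in each cubic voxel by their centroid. The
#' voxel edge length is found by bisection so the output size lands within
#' 10% of `target_count`.
#'
#' @param cloud a `point_cloud`, `slpc` or n x 3 matrix.
#' @param target_count requested number of output points (>= 4).
#' @param origin_jitter optional length-3 numeric in [0, 1): fractional shift
#'   of the voxel-grid origin (in voxel units), used to randomize repeated
#'   downsampling runs. Default no shift.
#' @return a `point_cloud` of voxel centroids. If `target_count` is not below
#'   the input size the input is returned unchanged with a warning when it
#'   exceeds it.
#' @export
voxel_downsample <- function(cloud, target_count, origin_jitter = c(0, 0, 0)) {
  P <- cloud_points(cloud)
  n <- nrow(P)
  if (target_count < 4) stop("target_count must be at least 4")
  if (target_count > n) {
    warning("target_count exceeds input size; returning input unchanged")
    return(point_cloud(P, "voxel_downsample passthrough"))
  }
  if (target_count == n) return(point_cloud(P, "voxel_downsample identity"))
  lo <- sweep(P, 2, apply(P, 2, min))
  ext <- max(apply(lo, 2, max))
  key_count <- function(h) {
    idx <- floor(sweep(lo / h, 2, origin_jitter, `+`))
    k <- (idx[, 1] * 2^20 + idx[, 2]) * 2^20 + idx[, 3]
    list(k = k, n = length(unique(k)))
  }
  h_lo <- ext / (2 * n^(1/3) + 10)   # small voxels: many cells
  h_hi <- 2 * ext                     # one cell
  # surface-like clouds occupy far fewer voxels than a volumetric cloud of
  # the same extent; shrink the lower bracket until the target is reachable
  while (key_count(h_lo)$n < target_count && h_lo > ext / 2^20)
    h_lo <- h_lo / 2
  best <- NULL
  for (it in 1:60) {
    h <- sqrt(h_lo * h_hi)
    kc <- key_count(h)
    if (is.null(best) ||
        abs(kc$n - target_count) < abs(best$n - target_count))
      best <- c(kc, h = h)
    if (abs(kc$n - target_count) <= 0.1 * target_count) break
    if (kc$n > target_count) h_lo <- h else h_hi <- h
  }
  grp <- match(best$k, unique(best$k))
  sums <- rowsum(P, grp, reorder = FALSE)
  cnts <- tabulate(grp)
  point_cloud(sums / cnts,
              sprintf("voxel_downsample h=%.4g -> %d points", best$h, best$n))
}
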