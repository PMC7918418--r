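#' Slice a standardized leaf cloud along the leaf axis
#'
#' Divides the x-extent of an SLPC into `nums` interior slices of equal
#' thickness `Ws = L / nums` with projection planes at the slice centers
#' `min(x) + (i - 0.5) Ws`, plus two zero-thickness boundary slices at the
#' leaf base (`plane = min(x)`) and tip (`plane = max(x)`). Membership uses
#' half-open x-intervals with the last interior interval closed, so every
#' point belongs to exactly one interior slice.
#'
#' @param slpc an `slpc` from [pca_normalize()] (or any cloud; it is used
#'   as-is, without re-normalization).
#' @param nums number of interior slices (>= 3).
#' @return an object of class `leaf_slices`: a list of `nums + 2` slices,
#'   each with fields `index` (0 .. nums+1), `plane_x`, `x_interval`,
#'   `thickness`, and `points`; plus attributes `Ws`, `nums`, `L`.
#' @export
slice_cloud <- function(slpc, nums) {
  if (nums < 3) stop("nums must be at least 3")
  nums <- as.integer(nums)
  P <- cloud_points(slpc)
  xmin <- min(P[, 1]); xmax <- max(P[, 1])
  L <- xmax - xmin
  Ws <- L / nums
  # interior membership: half-open [lo, hi), last interval closed
  bin <- pmin(pmax(floor((P[, 1] - xmin) / Ws) + 1L, 1L), nums)
  tol <- 1e-6 * L
  slices <- vector("list", nums + 2L)
  slices[[1]] <- list(index = 0L, plane_x = xmin,
                      x_interval = c(xmin, xmin), thickness = 0,
                      points = P[P[, 1] <= xmin + tol, , drop = FALSE])
  for (i in seq_len(nums)) {
    lo <- xmin + (i - 1) * Ws; hi <- xmin + i * Ws
    slices[[i + 1L]] <- list(index = i, plane_x = xmin + (i - 0.5) * Ws,
                             x_interval = c(lo, hi), thickness = Ws,
                             points = P[bin == i, , drop = FALSE])
  }
  slices[[nums + 2L]] <- list(index = nums + 1L, plane_x = xmax,
                              x_interval = c(xmax, xmax), thickness = 0,
                              points = P[P[, 1] >= xmax - tol, , drop = FALSE])
  empt <- sum(vapply(slices[2:(nums + 1L)],
                     function(s) nrow(s$points) == 0, logical(1)))
  if (empt > nums / 2)
    warning("more than half of the interior slices are empty; ",
            "nums is likely too large for this cloud")
  structure(slices, Ws = Ws, nums = as.integer(nums), L = L,
            xmin = xmin, xmax = xmax, class = "leaf_slices")
}

#' @export
print.leaf_slices <- function(x, ...) {
  cat(sprintf("Leaf slicing: %d interior slices of thickness %.3f mm (+ base/tip)\n",
              attr(x, "nums"), attr(x, "Ws")))
  invisible(x)
}

#' Per-slice summary table
#'
#' @param object a `leaf_slices`.
#' @param ... unused.
#' @return data frame with slice index, projection-plane x, and member count.
#' @export
summary.leaf_slices <- function(object, ...) {
  data.frame(index = vapply(object, `[[`, 0L, "index"),
             plane_x = vapply(object, `[[`, 0, "plane_x"),
             n_points = vapply(object, function(s) nrow(s$points), 0L))
}

feature_triple <- function(P_left, P_mid, P_right) {
  structure(list(P_left = P_left, P_mid = P_mid, P_right = P_right),
            class = "feature_triple")
}

#' Feature points of the leaf base
#'
#' Grows a slice from the leaf base (min x) in thickness steps of L/1000
#' until the y-range of its member points reaches the average petiole
#' diameter (2 mm). The left and right feature points take the minimum and
#' maximum y of that slice, the mean z of its points, and x = min(x); the
#' midrib point is their midpoint.
#'
#' @param slpc an `slpc` (base oriented at min(x)).
#' @param petiole_width y-range threshold in mm (default 2).
#' @return a `feature_triple` with fields `P_left`, `P_mid`, `P_right`.
#' @export
base_feature_points <- function(slpc, petiole_width = 2) {
  P <- cloud_points(slpc)
  xmin <- min(P[, 1])
  L <- diff(range(P[, 1]))
  step <- L / 1000
  for (k in seq_len(1000)) {
    sel <- P[, 1] <= xmin + k * step
    if (sum(sel) >= 2) {
      yr <- range(P[sel, 2])
      if (diff(yr) >= petiole_width) {
        zbar <- mean(P[sel, 3])
        pl <- c(xmin, yr[1], zbar)
        pr <- c(xmin, yr[2], zbar)
        return(feature_triple(pl, (pl + pr) / 2, pr))
      }
    }
  }
  stop("degenerate leaf: base slice never reaches a ", petiole_width,
       " mm y-range")
}

#' Feature point of the leaf tip
#'
#' The tip slice has zero thickness at max(x); its single feature point is
#' the mean of all cloud points within a 1e-6 * L band of max(x) (exact
#' float equality would be fragile). All three triple members coincide.
#'
#' @param slpc an `slpc`.
#' @return a `feature_triple` whose three members are identical.
#' @export
tip_feature_point <- function(slpc) {
  P <- cloud_points(slpc)
  xmax <- max(P[, 1])
  L <- diff(range(P[, 1]))
  sel <- P[, 1] >= xmax - 1e-6 * L
  pend <- colMeans(P[sel, , drop = FALSE])
  feature_triple(pend, pend, pend)
}

#' Select a uniformly distributed subset of slices
#'
#' Always includes the base (index 0) and tip (index nums+1) slices; the
#' remaining picks are a rounded uniform grid over the interior indices,
#' `floor(j (nums+1)/(count-1) + 0.5)` for `j = 1 .. count-2` (round half
#' away from zero), with collisions shifted to the nearest unused index.
#' With `nums = 50`, `count = 7` this yields indices 0, 9, 17, 26, 34, 43,
#' 51.
#'
#' @param slices a `leaf_slices`.
#' @param count total number of slices to keep (3 <= count <= nums + 2).
#' @return a `leaf_slices` of length `count` (attributes preserved).
#' @export
select_slices <- function(slices, count) {
  nums <- attr(slices, "nums")
  if (count < 3 || count > nums + 2)
    stop("count must be between 3 and nums + 2")
  if (count == nums + 2) return(slices)
  j <- seq_len(count - 2L)
  idx <- floor(j * (nums + 1) / (count - 1) + 0.5)
  idx <- pmin(pmax(idx, 1L), nums)
  # resolve rounding collisions
  for (k in seq_along(idx)[-1]) {
    while (idx[k] <= idx[k - 1] && idx[k] < nums) idx[k] <- idx[k] + 1L
  }
  if (anyDuplicated(idx)) stop("cannot place ", count, " distinct slices")
  keep <- c(0L, idx, nums + 1L)
  out <- slices[keep + 1L]
  attributes(out) <- c(attributes(out)[intersect(names(attributes(out)), "names")],
                       list(Ws = attr(slices, "Ws"), nums = nums,
                            L = attr(slices, "L"),
                            xmin = attr(slices, "xmin"),
                            xmax = attr(slices, "xmax"),
                            class = "leaf_slices"))
  out
}
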