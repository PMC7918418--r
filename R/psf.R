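#' Point sets to be fitted (PSF)
#'
#' A PSF is the slice-derived subset of the standardized cloud that the
#' surface is actually fitted to: a list of per-slice point columns running
#' left edge to right edge, ordered base to tip. In an *ordered* PSF every
#' column holds the same number of points (a regular grid); in an
#' *unordered* PSF interior columns hold all slice members projected onto
#' the slice's center plane, so column sizes differ.
#'
#' @name psf_generation
#' @keywords internal
NULL

new_psf <- function(columns, slice_indices = NULL, ordered = NA) {
  sizes <- vapply(columns, nrow, 0L)
  if (is.na(ordered)) ordered <- length(unique(sizes)) == 1L
  structure(list(columns = columns, slice_indices = slice_indices,
                 ordered = ordered),
            class = "psf")
}

#' @export
print.psf <- function(x, ...) {
  sizes <- vapply(x$columns, nrow, 0L)
  cat(sprintf("%s PSF: %d columns, %d points total (column sizes %s)\n",
              if (x$ordered) "Ordered" else "Unordered",
              length(x$columns), sum(sizes),
              paste(sizes, collapse = ",")))
  invisible(x)
}

#' Flatten a PSF to one point matrix
#'
#' @param psf a `psf`.
#' @return (total points) x 3 matrix, columns concatenated base to tip.
#' @export
psf_points <- function(psf) do.call(rbind, psf$columns)

#' Feature points of an interior slice
#'
#' Finds the leftmost (min y), highest (max z) and rightmost (max y) points
#' within the central band T of the slice (thickness Ws/2 around the
#' projection plane). If the band holds fewer than 3 points it is widened to
#' the full slice with a warning.
#'
#' @param slice one element of a `leaf_slices`.
#' @param Ws interior slice thickness (mm).
#' @return a `feature_triple`.
#' @export
interior_feature_points <- function(slice, Ws) {
  P <- slice$points
  band <- abs(P[, 1] - slice$plane_x) <= Ws / 4
  if (sum(band) < 3) {
    warning("fewer than 3 points in the central band of slice ",
            slice$index, "; widening to the full slice")
    band <- rep(TRUE, nrow(P))
  }
  Q <- P[band, , drop = FALSE]
  feature_triple(Q[argmin_tol(Q[, 2]), ],
                 Q[argmin_tol(-Q[, 3]), ],
                 Q[argmin_tol(-Q[, 2]), ])
}

# equally spaced seeds along the polyline P_left -> P_mid -> P_right:
# tl interior seeds on the left segment, tr on the right, plus the three
# feature points, ordered left to right
feature_seeds <- function(triple, tl, tr) {
  seg <- function(a, b, t) {
    s <- seq_len(t) / (t + 1)
    outer(1 - s, a) + outer(s, b)
  }
  rbind(matrix(triple$P_left, 1),
        seg(triple$P_left, triple$P_mid, tl),
        matrix(triple$P_mid, 1),
        seg(triple$P_mid, triple$P_right, tr),
        matrix(triple$P_right, 1))
}

#' Ordered column of points from one interior slice
#'
#' Builds the 3 + tl + tr seed points (features plus equally spaced points
#' between them) and replaces each by its Euclidean nearest neighbour among
#' the slice members. Duplicate nearest neighbours are kept.
#'
#' @param slice one element of a `leaf_slices`.
#' @param triple the slice's `feature_triple`.
#' @param tl,tr number of intermediate points left/right of the midrib
#'   (>= 1).
#' @return (3 + tl + tr) x 3 matrix ordered left to right.
#' @export
ordered_column <- function(slice, triple, tl, tr) {
  if (tl < 1 || tr < 1) stop("tl and tr must be at least 1")
  seeds <- feature_seeds(triple, tl, tr)
  P <- slice$points
  t(apply(seeds, 1, function(s) {
    P[argmin_tol(colSums((t(P) - s)^2)), ]
  }))
}

boundary_columns <- function(slpc, tl, tr) {
  base <- feature_seeds(base_feature_points(slpc), tl, tr)
  tipt <- tip_feature_point(slpc)
  k1 <- 3L + tl + tr
  tip <- matrix(tipt$P_left, k1, 3, byrow = TRUE)
  list(base = base, tip = tip)
}

#' Build an ordered PSF
#'
#' One column of `3 + tl + tr` points per selected slice: the base column
#' uses the base feature points and their equally spaced intermediates
#' directly, interior columns snap seeds to nearest slice members
#' ([ordered_column()]), and the tip column repeats the tip point.
#'
#' @param slpc an `slpc`.
#' @param selected a `leaf_slices` from [select_slices()] (must contain the
#'   base and tip slices).
#' @param tl,tr intermediate point counts (default 2 each, giving 7-point
#'   columns).
#' @return an ordered `psf` with `length(selected)` columns.
#' @export
build_ordered_psf <- function(slpc, selected, tl = 2, tr = 2) {
  Ws <- attr(selected, "Ws")
  bc <- boundary_columns(slpc, tl, tr)
  ncol_ <- length(selected)
  cols <- vector("list", ncol_)
  cols[[1]] <- bc$base
  cols[[ncol_]] <- bc$tip
  for (j in seq(2, ncol_ - 1)) {
    sl <- selected[[j]]
    if (nrow(sl$points) < 3)
      stop("selected slice ", sl$index, " has fewer than 3 points")
    cols[[j]] <- ordered_column(sl, interior_feature_points(sl, Ws), tl, tr)
  }
  new_psf(cols, slice_indices = vapply(selected, `[[`, 0L, "index"),
          ordered = TRUE)
}

#' Build an unordered PSF
#'
#' Interior columns take *all* member points of each selected slice,
#' projected along the leaf axis onto the slice's center plane (x replaced
#' by the plane coordinate, y and z unchanged) and sorted left to right by
#' y. The base and tip columns are identical to the ordered construction.
#'
#' @inheritParams build_ordered_psf
#' @return an unordered `psf`.
#' @export
build_unordered_psf <- function(slpc, selected, tl = 2, tr = 2) {
  bc <- boundary_columns(slpc, tl, tr)
  ncol_ <- length(selected)
  cols <- vector("list", ncol_)
  cols[[1]] <- bc$base
  cols[[ncol_]] <- bc$tip
  for (j in seq(2, ncol_ - 1)) {
    sl <- selected[[j]]
    P <- sl$points
    if (nrow(P) == 0)
      stop("selected interior slice ", sl$index, " is empty")
    P[, 1] <- sl$plane_x
    cols[[j]] <- P[order(P[, 2]), , drop = FALSE]
  }
  new_psf(cols, slice_indices = vapply(selected, `[[`, 0L, "index"),
          ordered = FALSE)
}

#' Build the evaluation test subset
#'
#' An ordered PSF used only for error measurement: the cloud is re-sliced so
#' that `n_slices` total columns (including base and tip) of `per_slice`
#' points each are extracted, `per_slice = 3 + tl + tr` with `tl = tr`.
#' The default 10 columns x 9 points gives a 90-point subset.
#'
#' @param slpc an `slpc`.
#' @param n_slices total number of columns including base and tip
#'   (default 10).
#' @param per_slice points per column (default 9; must be odd and >= 5 so
#'   that `tl = tr = (per_slice - 3) / 2` are positive integers).
#' @return an ordered `psf` with `n_slices * per_slice` points.
#' @export
build_test_subset <- function(slpc, n_slices = 10, per_slice = 9) {
  t2 <- (per_slice - 3) / 2
  if (t2 != round(t2) || t2 < 1)
    stop("per_slice must equal 3 + 2t for an integer t >= 1")
  slices <- slice_cloud(slpc, n_slices - 2L)
  build_ordered_psf(slpc, select_slices(slices, n_slices),
                    tl = t2, tr = t2)
}
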