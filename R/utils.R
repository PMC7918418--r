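# internal helpers

# coerce to an n x 3 numeric matrix with columns x, y, z
as_xyz <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, 1:3])
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = FALSE)
  if (ncol(x) < 3) stop("points must have 3 coordinates")
  m <- unname(as.matrix(x[, 1:3, drop = FALSE]))
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("non-finite coordinates in point set")
  m
}

# index of the minimum with deterministic near-tie breaking: among values
# within a small absolute band of the minimum, take the first. Plain
# which.min is unstable across runs when two candidates are numerically
# tied and the inputs carry ~1e-14 coordinate noise.
argmin_tol <- function(x, tol = 1e-7) {
  m <- min(x)
  which(x <= m + tol * (1 + abs(m)))[1]
}

# run expr with a temporary RNG seed, restoring the caller's RNG state;
# seed = NULL uses the current stream untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
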