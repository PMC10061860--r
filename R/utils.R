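# Run code under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Distance from each row of `query` to its nearest row of `ref` (both N x 3).
# A positive cap bounds the search; farther points report exactly `cap`, so
# callers must use a cap strictly larger than any threshold they compare to.
nn_dist_to_set <- function(query, ref, cap = -1) {
  cpp_nn_to_set(query, ref, cap)$dist
}

# Index (into ref) of the nearest row of `ref` for each row of `query`.
nn_index_to_set <- function(query, ref) {
  cpp_nn_to_set(query, ref)$index
}

# Rodrigues rotation matrix taking unit vector `a` onto unit vector `b`,
# rotating about the axis a x b. Handles the parallel and antiparallel cases.
rotation_align <- function(a, b) {
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2))
  cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any axis orthogonal to a
    u <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- u - sum(u * a) * a
    u <- u / sqrt(sum(u^2))
    return(2 * tcrossprod(u) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2],
                 v[3], 0, -v[1],
                 -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
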