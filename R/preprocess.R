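#' Statistical outlier removal
#'
#' Classic SOR denoising: for every point the mean Euclidean distance to its
#' `k` nearest neighbors (excluding the point itself) is computed; points whose
#' mean distance exceeds `mean(d) + std_mult * sd(d)` over the whole cloud are
#' removed. Single pass; labels and colors follow their points.
#'
#' @param cloud a [plant_cloud()] with more than `k` points.
#' @param k number of nearest neighbors (default 6).
#' @param std_mult standard-deviation multiplier of the removal threshold
#'   (default 1).
#' @return A list with `cloud` (the denoised [plant_cloud()]) and `removed`
#'   (integer indices of removed points in the input cloud).
#' @export
#' @examples
#' g <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2)) * 0.01
#' pc <- plant_cloud(rbind(g, c(1, 1, 1)))
#' sor_denoise(pc)$removed
sor_denoise <- function(cloud, k = 6L, std_mult = 1.0) {
  stopifnot(inherits(cloud, "plant_cloud"))
  if (k < 1 || std_mult <= 0) stop("k and std_mult must be positive")
  if (n_points(cloud) <= k)
    stop("cloud must contain more than k points")
  d <- cpp_knn_mean_dist(cloud$coords, as.integer(k))
  thr <- mean(d) + std_mult * sd(d)
  removed <- which(d > thr)
  keep <- if (length(removed)) -removed else seq_len(n_points(cloud))
  list(cloud = subset_cloud(cloud, keep), removed = removed)
}

#' Normalize a cloud to the unit sphere
#'
#' Subtracts the centroid of all points and divides by the maximum point norm,
#' so the output cloud is centered at the origin with radius exactly 1. The
#' returned state allows exact inversion with [denormalize_cloud()].
#'
#' @param cloud a [plant_cloud()] with at least one point off its centroid.
#' @return A list with `cloud` (normalized) and `state`, a `norm_state` object
#'   holding `centroid` (meters) and `scale` (meters, the max centered norm).
#' @export
#' @examples
#' pc <- plant_cloud(cbind(0, 0, c(0, 2)))
#' normalize_cloud(pc)$cloud$coords
normalize_cloud <- function(cloud) {
  stopifnot(inherits(cloud, "plant_cloud"))
  centroid <- colMeans(cloud$coords)
  centered <- sweep(cloud$coords, 2, centroid)
  scale <- sqrt(max(rowSums(centered^2)))
  if (scale <= 0)
    stop("degenerate cloud: all points identical")
  out <- cloud
  out$coords <- centered / scale
  dimnames(out$coords) <- list(NULL, c("x", "y", "z"))
  list(cloud = out,
       state = structure(list(centroid = centroid, scale = scale),
                         class = "norm_state"))
}

#' Invert unit-sphere normalization
#'
#' @param cloud a normalized [plant_cloud()].
#' @param state the `norm_state` returned by [normalize_cloud()].
#' @return The denormalized [plant_cloud()], with coordinates back in meters.
#' @export
denormalize_cloud <- function(cloud, state) {
  stopifnot(inherits(cloud, "plant_cloud"), inherits(state, "norm_state"))
  out <- cloud
  out$coords <- sweep(cloud$coords * state$scale, 2, state$centroid, `+`)
  dimnames(out$coords) <- list(NULL, c("x", "y", "z"))
  out
}

#' @export
print.norm_state <- function(x, ...) {
  cat(sprintf("<norm_state> centroid (%.4f, %.4f, %.4f) m, scale %.4f m\n",
              x$centroid[1], x$centroid[2], x$centroid[3], x$scale))
  invisible(x)
}

#' Save / load a normalization state sidecar
#'
#' The state is stored as a small JSON file (`centroid`, `scale`) so that
#' normalized clouds written to disk can later be mapped back to meters.
#'
#' @param state a `norm_state`.
#' @param path JSON file path.
#' @return `write_norm_state`: the path, invisibly. `read_norm_state`: the
#'   `norm_state`.
#' @export
write_norm_state <- function(state, path) {
  stopifnot(inherits(state, "norm_state"))
  jsonlite::write_json(list(centroid = state$centroid, scale = state$scale),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_norm_state
#' @export
read_norm_state <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(centroid = as.numeric(x$centroid), scale = as.numeric(x$scale)),
            class = "norm_state")
}

#' Random down-sampling
#'
#' Uniform random subset of exactly `n` points without replacement; clouds
#' with at most `n` points are returned unchanged. Reproducible under `seed`.
#'
#' @param cloud a [plant_cloud()].
#' @param n target point count (default 100000).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return The down-sampled [plant_cloud()].
#' @export
random_downsample <- function(cloud, n = 100000L, seed = NULL) {
  stopifnot(inherits(cloud, "plant_cloud"))
  if (n < 1) stop("n must be >= 1")
  if (n_points(cloud) <= n) return(cloud)
  keep <- with_seed(seed, sample.int(n_points(cloud), n))
  subset_cloud(cloud, sort(keep))
}
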