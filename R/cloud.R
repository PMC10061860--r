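#' Labeled plant point cloud
#'
#' Container for a single-plant 3D point cloud: an N x 3 coordinate matrix in
#' meters (z vertical, up), optional per-point RGB colors (integers 0-255) and
#' optional per-point part labels (`0` main stem, `1` branch, `2` boll, `-1`
#' unlabeled).
#'
#' @param coords N x 3 numeric matrix of point coordinates in meters
#'   (columns x, y, z; z is the vertical axis).
#' @param colors optional N x 3 integer matrix of RGB colors in 0-255.
#' @param labels optional integer vector of length N with values in
#'   \{-1, 0, 1, 2\}.
#'
#' @return An object of class `plant_cloud`: a list with elements `coords`,
#'   `colors` (or `NULL`) and `labels` (or `NULL`).
#' @export
#' @examples
#' pc <- plant_cloud(cbind(0, 0, c(0, 0.5, 1)), labels = c(0L, 0L, 1L))
#' pc
plant_cloud <- function(coords, colors = NULL, labels = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3)
    stop("coords must have 3 columns (x, y, z)")
  if (nrow(coords) < 1)
    stop("cloud must contain at least one point")
  if (!all(is.finite(coords)))
    stop("coords must be finite")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    storage.mode(colors) <- "integer"
    if (ncol(colors) != 3 || nrow(colors) != nrow(coords))
      stop("colors must be an N x 3 matrix matching coords")
    if (anyNA(colors) || any(colors < 0L) || any(colors > 255L))
      stop("color channels must be integers in [0, 255]")
    dimnames(colors) <- list(NULL, c("r", "g", "b"))
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(coords))
      stop("labels must have one value per point")
    if (anyNA(labels) || !all(labels %in% c(-1L, 0L, 1L, 2L)))
      stop("labels must be in {-1, 0, 1, 2}")
  }
  structure(list(coords = coords, colors = colors, labels = labels),
            class = "plant_cloud")
}

#' @export
print.plant_cloud <- function(x, ...) {
  cat(sprintf("<plant_cloud> %d points", nrow(x$coords)))
  if (!is.null(x$colors)) cat(", RGB")
  if (!is.null(x$labels)) {
    tab <- table(factor(x$labels, levels = c(-1L, 0L, 1L, 2L)))
    cat(sprintf(", labels [stem %d | branch %d | boll %d | none %d]",
                tab[["0"]], tab[["1"]], tab[["2"]], tab[["-1"]]))
  }
  rng <- apply(x$coords, 2, range)
  cat(sprintf("\n  extent (m): x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Number of points in a cloud
#'
#' @param cloud a [plant_cloud()].
#' @return Integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "plant_cloud"))
  nrow(cloud$coords)
}

# subset a cloud by point index, keeping colors/labels aligned
subset_cloud <- function(cloud, keep) {
  plant_cloud(cloud$coords[keep, , drop = FALSE],
              colors = if (!is.null(cloud$colors)) cloud$colors[keep, , drop = FALSE],
              labels = if (!is.null(cloud$labels)) cloud$labels[keep])
}

require_labels <- function(cloud) {
  if (is.null(cloud$labels))
    stop("this operation requires a labeled cloud", call. = FALSE)
  invisible(cloud)
}

# convert labels {0,1,2} to convention colors; others gray
labels_to_colors <- function(labels) {
  n <- length(labels)
  cols <- matrix(128L, n, 3)
  for (lab in 0:2) {
    sel <- labels == lab
    if (any(sel)) cols[sel, ] <- matrix(LABEL_COLORS[lab + 1L, ], sum(sel), 3, byrow = TRUE)
  }
  cols
}

# infer labels from pure convention colors; anything else -> -1
colors_to_labels <- function(colors) {
  labels <- rep(-1L, nrow(colors))
  for (lab in 0:2) {
    ref <- LABEL_COLORS[lab + 1L, ]
    sel <- colors[, 1] == ref[1] & colors[, 2] == ref[2] & colors[, 3] == ref[3]
    labels[sel] <- lab
  }
  labels
}
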