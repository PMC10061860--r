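#' Slice-wise main-stem/branch label correction
#'
#' Corrects the stem/branch confusion typical of semantic segmentation output.
#' The bottom-most `slice_height` slice of main-stem points - assumed to be
#' predicted correctly - anchors an x/y bounding rectangle. Slices of height
#' `slice_height` are then walked up the z axis, up to the topmost slice
#' containing a main-stem point; in each slice, branch-labeled points lying
#' inside the previous slice's rectangle expanded by `margin` are relabeled
#' main stem, and main-stem-labeled points lying outside it are relabeled
#' branch. The rectangle is then updated from the slice's post-correction
#' main-stem points (carried forward unchanged when a slice has none). The
#' walk rests on the assumption that a stem cannot change its growing
#' direction by more than `margin` per slice. The procedure is repeated once
#' per entry of `margins` (two rounds with slightly different margins by
#' default). Boll and unlabeled points, and all coordinates, are never
#' touched.
#'
#' The corridor drifts more slowly than it admits: the rectangle is updated
#' only from post-correction main-stem points lying within the previous
#' rectangle expanded by half the margin. Points relabeled near the margin's
#' edge (typically at branch attachments) therefore join the stem without
#' dragging the corridor after them; without this damping the corridor can
#' chase a branch upward at up to `sqrt(2) * margin` per slice along a
#' diagonal - faster than any branch steeper than about 35 degrees recedes -
#' and swallow it. With the damping the corridor still tracks stems that
#' drift up to `margin / 2` per slice (about 27 degrees off vertical at the
#' defaults, ample for curved or tilted stems) and cannot follow branches
#' inclined below about 50 degrees.
#'
#' @param cloud a labeled [plant_cloud()] in meters with at least one
#'   main-stem point.
#' @param slice_height slice height in meters (default 1 cm).
#' @param margins numeric vector of per-round margins in meters
#'   (default 1.0 cm then 1.2 cm).
#' @return The corrected [plant_cloud()].
#' @export
correct_stem_branch <- function(cloud, slice_height = 0.01,
                                margins = c(0.010, 0.012)) {
  require_labels(cloud)
  if (!any(cloud$labels == LABEL_STEM))
    stop("label correction requires at least one main-stem point")
  if (slice_height <= 0 || any(margins <= 0))
    stop("slice_height and margins must be positive")
  labels <- cloud$labels
  for (m in margins)
    labels <- correct_round(cloud$coords, labels, slice_height, m)
  cloud$labels <- labels
  cloud
}

correct_round <- function(xyz, labels, h, margin) {
  stem <- labels == LABEL_STEM
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  z0 <- min(z[stem])
  top_slice <- floor((max(z[stem]) - z0) / h)
  si <- floor((z - z0) / h)
  movable <- labels == LABEL_STEM | labels == LABEL_BRANCH
  active <- movable & si >= 0 & si <= top_slice
  slice_idx <- split(which(active), si[active])

  bottom <- slice_idx[["0"]]
  b0 <- bottom[labels[bottom] == LABEL_STEM]
  bounds <- c(range(x[b0]), range(y[b0]))
  for (s in seq_len(top_slice)) {
    idx <- slice_idx[[as.character(s)]]
    if (is.null(idx)) next
    inside <- x[idx] >= bounds[1] - margin & x[idx] <= bounds[2] + margin &
      y[idx] >= bounds[3] - margin & y[idx] <= bounds[4] + margin
    lab <- labels[idx]
    lab[inside & lab == LABEL_BRANCH] <- LABEL_STEM
    lab[!inside & lab == LABEL_STEM] <- LABEL_BRANCH
    labels[idx] <- lab
    # corridor drift is damped: only stem points within half a margin of the
    # previous rectangle move the bounds
    follow <- margin / 2
    snow <- idx[lab == LABEL_STEM &
                  x[idx] >= bounds[1] - follow & x[idx] <= bounds[2] + follow &
                  y[idx] >= bounds[3] - follow & y[idx] <= bounds[4] + follow]
    if (length(snow))
      bounds <- c(range(x[snow]), range(y[snow]))
  }
  labels
}
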