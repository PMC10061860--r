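#' Main stem height
#'
#' Vertical height of the segmented main stem: the difference between the
#' highest and lowest z among main-stem-labeled points. This is deliberately
#' not the plant height (branches may overtop the stem) nor the arc length of
#' a curved stem.
#'
#' @param cloud a labeled [plant_cloud()] in meters with at least two
#'   main-stem points.
#' @return Height in meters.
#' @export
stem_height <- function(cloud) {
  require_labels(cloud)
  z <- cloud$coords[cloud$labels == LABEL_STEM, 3]
  if (length(z) < 2) stop("need at least two main-stem points")
  max(z) - min(z)
}

#' Pratt algebraic circle fit
#'
#' Fits a circle to 2D points by the Pratt method: minimize the algebraic
#' distance \eqn{\sum (A(x^2+y^2) + Bx + Cy + D)^2} subject to the
#' normalization \eqn{B^2 + C^2 - 4AD = 1}, solved as a generalized
#' eigenproblem on the moment matrix. Exact on noiseless circles (including
#' three non-collinear points) and nearly unbiased for small noise.
#'
#' @param points M x 2 matrix, M >= 3, not all collinear.
#' @return A list with `center` (length-2) and `radius`.
#' @export
#' @examples
#' fit_circle_pratt(rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)))
fit_circle_pratt <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 3)
    stop("need at least 3 points with 2 columns")
  ctr <- colMeans(points)
  u <- points[, 1] - ctr[1]
  v <- points[, 2] - ctr[2]
  z <- u * u + v * v
  Zm <- cbind(z, u, v, 1)
  M <- crossprod(Zm) / nrow(points)
  Bc <- matrix(c(0, 0, 0, -2,
                 0, 1, 0, 0,
                 0, 0, 1, 0,
                 -2, 0, 0, 0), 4, 4, byrow = TRUE)
  ev <- eigen(solve(Bc, M))
  vals <- ev$values
  keep <- abs(Im(vals)) < 1e-8 * (1 + abs(Re(vals)))
  vals <- Re(vals)[keep]
  vecs <- Re(ev$vectors)[, keep, drop = FALSE]
  # smallest eigenvalue >= 0 (up to rounding) gives the Pratt solution
  tol <- -1e-9 * max(1, abs(vals))
  ok <- which(vals >= tol)
  if (!length(ok)) stop("circle fit failed: no admissible eigenvalue")
  sol <- ok[which.min(vals[ok])]
  p <- vecs[, sol]
  A <- p[1]; B <- p[2]; C <- p[3]; D <- p[4]
  disc <- B * B + C * C - 4 * A * D
  if (abs(A) < 1e-12 * sqrt(sum(p^2)) || disc <= 0)
    stop("degenerate circle fit (collinear points?)")
  list(center = c(-B / (2 * A) + ctr[1], -C / (2 * A) + ctr[2]),
       radius = sqrt(disc) / (2 * abs(A)))
}

#' Main stem diameter
#'
#' Projects the main-stem points of the lowest `slice_height` region onto the
#' xy plane and fits a circle by the Pratt method; the diameter is twice the
#' fitted radius.
#'
#' @param cloud a labeled [plant_cloud()] in meters.
#' @param slice_height height in meters of the bottom slice (default 1 cm).
#' @return Diameter in meters.
#' @export
stem_diameter <- function(cloud, slice_height = 0.01) {
  require_labels(cloud)
  stem <- cloud$labels == LABEL_STEM
  if (!any(stem)) stop("no main-stem points")
  z <- cloud$coords[, 3]
  z0 <- min(z[stem])
  sel <- stem & z <= z0 + slice_height
  if (sum(sel) < 3) stop("fewer than 3 main-stem points in the bottom slice")
  2 * fit_circle_pratt(cloud$coords[sel, 1:2, drop = FALSE])$radius
}

# DBSCAN cluster assignment for boll-labeled points plus retention filter.
# Returns indices into the cloud, the cluster id per boll point (0 = noise),
# and a per-cluster summary with the 3 cm height filter applied.
boll_clusters <- function(cloud, eps = 0.005, min_pts = 100L,
                          min_height = 0.03) {
  require_labels(cloud)
  idx <- which(cloud$labels == LABEL_BOLL)
  if (!length(idx))
    return(list(index = integer(0), cluster = integer(0),
                summary = data.frame(id = integer(0), size = integer(0),
                                     z_extent = numeric(0),
                                     z_max = numeric(0),
                                     retained = logical(0))))
  cl <- cpp_dbscan(cloud$coords[idx, , drop = FALSE], eps, as.integer(min_pts))
  ids <- sort(unique(cl[cl > 0]))
  z <- cloud$coords[idx, 3]
  summ <- do.call(rbind, lapply(ids, function(k) {
    sel <- cl == k
    data.frame(id = k, size = sum(sel),
               z_extent = max(z[sel]) - min(z[sel]),
               z_max = max(z[sel]))
  }))
  if (is.null(summ))
    summ <- data.frame(id = integer(0), size = integer(0),
                       z_extent = numeric(0), z_max = numeric(0))
  summ$retained <- summ$z_extent >= min_height
  list(index = idx, cluster = cl, summary = summ)
}

#' Count cotton bolls
#'
#' Clusters boll-labeled points with DBSCAN (`eps` 5 mm, `min_pts` 100),
#' removes clusters whose z-extent is below 3 cm (immature bolls and floral
#' "squares"), and counts one boll per cluster. Clusters whose size exceeds
#' Q3 + `iqr_mult` * IQR of the retained cluster sizes are treated as several
#' connected bolls and count `round(size / mean cluster size)`.
#'
#' @param cloud a labeled [plant_cloud()] in meters.
#' @param eps DBSCAN neighborhood radius in meters.
#' @param min_pts DBSCAN density threshold (neighbor count including the
#'   point itself).
#' @param min_height minimum cluster z-extent in meters.
#' @param iqr_mult multiplier of the interquartile range in the outlier rule.
#' @param divisor_includes_outliers whether the mean cluster size used as the
#'   divisor for outlier clusters includes the outlier clusters themselves
#'   (the default, a literal reading of the counting rule).
#' @return A list: `n_bolls` (integer), `clusters` (per-retained-cluster
#'   data.frame with `size`, `z_extent`, `outlier`, `count`), and
#'   `outlier_counts` (boll counts assigned to outlier clusters).
#' @export
count_bolls <- function(cloud, eps = 0.005, min_pts = 100L, min_height = 0.03,
                        iqr_mult = 1.5, divisor_includes_outliers = TRUE) {
  bc <- boll_clusters(cloud, eps, min_pts, min_height)
  summ <- bc$summary[bc$summary$retained, , drop = FALSE]
  if (nrow(summ) == 0)
    return(list(n_bolls = 0L,
                clusters = data.frame(size = integer(0), z_extent = numeric(0),
                                      outlier = logical(0), count = integer(0)),
                outlier_counts = integer(0)))
  sizes <- summ$size
  q <- quantile(sizes, c(0.25, 0.75), names = FALSE)
  thr <- q[2] + iqr_mult * (q[2] - q[1])
  outlier <- sizes > thr
  divisor <- if (divisor_includes_outliers) mean(sizes) else {
    if (all(outlier)) mean(sizes) else mean(sizes[!outlier])
  }
  count <- ifelse(outlier, pmax(1L, as.integer(round(sizes / divisor))), 1L)
  list(n_bolls = as.integer(sum(count)),
       clusters = data.frame(size = sizes, z_extent = summ$z_extent,
                             outlier = outlier, count = as.integer(count)),
       outlier_counts = as.integer(count[outlier]))
}

#' Detect branches
#'
#' Two-stage DBSCAN procedure on a labeled cloud in meters:
#' \enumerate{
#'   \item Branch and boll points are clustered together (DBSCAN, `eps` 2 cm,
#'     `min_pts` 100) and clusters of fewer than 100 points are discarded,
#'     removing tiny branches.
#'   \item Surviving branch-labeled points within 2 cm of the nearest
#'     main-stem point are selected, and DBSCAN (`eps` 2 cm, `min_pts` 10) on
#'     the selection yields one cluster per detected branch.
#'   \item The attachment location is the mean of cluster points within 1 cm
#'     of the stem (or, if the scan leaves a gap at the junction, of the
#'     points within 5 mm of the closest approach).
#'   \item Branches attaching above the uppermost retained boll cluster are
#'     dropped (regrowth above the uppermost boll is not counted).
#'   \item For angle and diameter estimation each cluster is extended to the
#'     branch points within 6 cm of the stem, using connectivity: a DBSCAN
#'     component of the 6 cm selection extends the cluster it contains, and
#'     nearest-selected-point assignment resolves components containing
#'     several clusters.
#' }
#'
#' @param cloud a labeled [plant_cloud()] in meters.
#' @param eps DBSCAN neighborhood radius in meters (both stages).
#' @param min_cluster minimum size of a branch+boll cluster in stage 1.
#' @param attach_radius selection radius around the stem in meters.
#' @param attach_avg_radius radius in meters for averaging the attachment
#'   location.
#' @param angle_radius extension radius in meters for angle/diameter points.
#' @param cluster_min_pts DBSCAN density threshold for the per-branch stage.
#' @param boll_cutoff apply the uppermost-boll exclusion rule (ignored when
#'   the cloud has no retained boll cluster).
#' @param boll_eps,boll_min_pts,boll_min_height boll clustering parameters
#'   used for the cutoff, as in [count_bolls()].
#' @return A list of `branch_record` objects with elements `cluster_indices`,
#'   `member_indices` (indices into the cloud), `points` (member
#'   coordinates), `attachment` (3-vector), and `min_z`.
#' @export
detect_branches <- function(cloud, eps = 0.02, min_cluster = 100L,
                            attach_radius = 0.02, attach_avg_radius = 0.01,
                            angle_radius = 0.06, cluster_min_pts = 10L,
                            boll_cutoff = TRUE, boll_eps = 0.005,
                            boll_min_pts = 100L, boll_min_height = 0.03) {
  require_labels(cloud)
  labels <- cloud$labels
  stem_xyz <- cloud$coords[labels == LABEL_STEM, , drop = FALSE]
  if (nrow(stem_xyz) == 0) stop("no main-stem points")
  branch_or_boll <- which(labels %in% c(LABEL_BRANCH, LABEL_BOLL))
  if (!any(labels == LABEL_BRANCH)) return(list())

  # stage 1: filter out tiny branches
  cl1 <- cpp_dbscan(cloud$coords[branch_or_boll, , drop = FALSE], eps,
                    as.integer(min_cluster))
  keep_ids <- which(tabulate(cl1[cl1 > 0]) >= min_cluster)
  retained <- branch_or_boll[cl1 %in% keep_ids &
                               labels[branch_or_boll] == LABEL_BRANCH]
  if (!length(retained)) return(list())

  # stage 2: per-branch clustering of the near-stem selection
  d_stem <- nn_dist_to_set(cloud$coords[retained, , drop = FALSE], stem_xyz,
                           cap = 2 * angle_radius)
  sel <- retained[d_stem <= attach_radius]
  if (length(sel) < cluster_min_pts) return(list())
  cl2 <- cpp_dbscan(cloud$coords[sel, , drop = FALSE], eps,
                    as.integer(cluster_min_pts))
  ids <- sort(unique(cl2[cl2 > 0]))
  if (!length(ids)) return(list())

  # uppermost-boll cutoff
  z_cut <- Inf
  if (boll_cutoff) {
    bs <- boll_clusters(cloud, boll_eps, boll_min_pts, boll_min_height)$summary
    if (any(bs$retained)) z_cut <- max(bs$z_max[bs$retained])
  }

  # member extension to angle_radius: each detected branch is grown to the
  # connected component (DBSCAN at the same eps) of the 6 cm selection that
  # contains its cluster; nearest-selected-point assignment is used only
  # where components merge, so outer points of one branch cannot be grafted
  # onto an equidistant neighbor
  ext <- retained[d_stem <= angle_radius]
  cl6 <- cpp_dbscan(cloud$coords[ext, , drop = FALSE], eps,
                    as.integer(cluster_min_pts))
  ext_cl2 <- integer(length(ext))
  ext_cl2[match(sel, ext)] <- cl2
  ext_cl <- integer(length(ext))
  for (g in unique(cl6[cl6 > 0])) {
    ing <- which(cl6 == g)
    ids2 <- setdiff(unique(ext_cl2[ing]), 0L)
    if (length(ids2) == 1L) {
      ext_cl[ing] <- ids2
    } else if (length(ids2) > 1L) {
      near <- nn_index_to_set(cloud$coords[ext[ing], , drop = FALSE],
                              cloud$coords[sel, , drop = FALSE])
      ext_cl[ing] <- cl2[near]
    }  # components without a selected point stay unassigned
  }
  lone <- which(cl6 == 0L)
  if (length(lone)) {
    near <- nn_index_to_set(cloud$coords[ext[lone], , drop = FALSE],
                            cloud$coords[sel, , drop = FALSE])
    ext_cl[lone] <- cl2[near]
  }

  d_sel <- d_stem[d_stem <= attach_radius]
  records <- list()
  for (k in ids) {
    cidx <- sel[cl2 == k]
    dk <- d_sel[cl2 == k]
    avg_sel <- dk <= attach_avg_radius
    if (!any(avg_sel)) avg_sel <- dk <= min(dk) + 0.005
    attachment <- colMeans(cloud$coords[cidx[avg_sel], , drop = FALSE])
    if (attachment[3] > z_cut) next
    midx <- ext[ext_cl == k]
    records[[length(records) + 1]] <- structure(list(
      cluster_indices = cidx,
      member_indices = midx,
      points = cloud$coords[midx, , drop = FALSE],
      attachment = attachment,
      min_z = min(cloud$coords[cidx, 3])
    ), class = "branch_record")
  }
  records
}

# dominant principal axis of a point set, sign fixed so the z-component is
# non-negative
branch_axis <- function(points) {
  if (nrow(points) < 3) stop("need at least 3 points for the principal axis")
  pc <- prcomp(points, center = TRUE, scale. = FALSE)
  if (pc$sdev[1] <= 1e-12 ||
      (length(pc$sdev) > 1 && pc$sdev[2] / pc$sdev[1] > 0.999))
    stop("degenerate cluster: dominant axis undefined")
  a <- pc$rotation[, 1]
  if (a[3] < 0) a <- -a
  a / sqrt(sum(a^2))
}

#' Branch inclination angle
#'
#' PCA is applied to the member points of a detected branch; the inclination
#' is the angle in degrees between the dominant principal component and its
#' projection on the horizontal (xy) plane: 0 = horizontal, 90 = vertical.
#'
#' @param record a `branch_record` from [detect_branches()].
#' @return Inclination in degrees in \[0, 90\].
#' @export
branch_inclination <- function(record) {
  stopifnot(inherits(record, "branch_record"))
  a <- branch_axis(record$points)
  unname(atan2(abs(a[3]), sqrt(a[1]^2 + a[2]^2)) * 180 / pi)
}

#' Branch diameter
#'
#' The branch member points are rotated so that the dominant principal
#' component aligns with the z axis (Rodrigues rotation about the axis
#' \eqn{A \times z}), the bottom-most `slice_height` slice of the rotated
#' points is projected on the xy plane, and a Pratt circle fit gives the
#' diameter, mirroring the main-stem procedure.
#'
#' @param record a `branch_record` from [detect_branches()].
#' @param slice_height slice height in meters (default 1 cm).
#' @return Diameter in meters.
#' @export
branch_diameter <- function(record, slice_height = 0.01) {
  stopifnot(inherits(record, "branch_record"))
  a <- branch_axis(record$points)
  R <- rotation_align(a, c(0, 0, 1))
  rot <- record$points %*% t(R)
  z0 <- min(rot[, 3])
  sel <- rot[, 3] <= z0 + slice_height
  if (sum(sel) < 3) stop("fewer than 3 points in the bottom branch slice")
  2 * fit_circle_pratt(rot[sel, 1:2, drop = FALSE])$radius
}

#' Detect nodes from branch clusters
#'
#' Branch clusters are sorted by their minimum z; walking up the sorted list,
#' a cluster joins the current node when its minimum is within `tol` (1 cm) of
#' the previous cluster's minimum, otherwise it starts a new node. A node's
#' location is the average over its member clusters of the mean of main-stem
#' points in the 1 cm stem slice above each cluster's minimum.
#'
#' @param branches list of `branch_record`s from [detect_branches()].
#' @param cloud the labeled [plant_cloud()] the branches came from.
#' @param tol same-node tolerance in meters.
#' @param slice_height stem slice height in meters for node locations.
#' @return A list with `n_nodes`, `node_locations` (n_nodes x 3 matrix), and
#'   `node_of` (node id per branch, in the input branch order).
#' @export
detect_nodes <- function(branches, cloud, tol = 0.01, slice_height = 0.01) {
  if (length(branches) == 0)
    return(list(n_nodes = 0L, node_locations = matrix(numeric(0), 0, 3),
                node_of = integer(0)))
  require_labels(cloud)
  mz <- vapply(branches, `[[`, 0, "min_z")
  ord <- order(mz)
  node_of <- integer(length(branches))
  node <- 0L
  prev <- -Inf
  for (i in ord) {
    if (mz[i] - prev > tol) node <- node + 1L
    node_of[i] <- node
    prev <- mz[i]
  }
  stem <- cloud$labels == LABEL_STEM
  sxyz <- cloud$coords[stem, , drop = FALSE]
  loc <- t(vapply(seq_len(node), function(k) {
    slices <- vapply(which(node_of == k), function(i) {
      sel <- sxyz[, 3] >= mz[i] & sxyz[, 3] <= mz[i] + slice_height
      if (!any(sel)) return(c(NA_real_, NA_real_, NA_real_))
      colMeans(sxyz[sel, , drop = FALSE])
    }, numeric(3))
    rowMeans(slices, na.rm = TRUE)
  }, numeric(3)))
  list(n_nodes = node, node_locations = loc, node_of = node_of)
}

#' Extract the seven architectural traits
#'
#' Composes the trait extractors into one record: main stem height and
#' diameter, number of branches, number of nodes (with locations), per-branch
#' inclination angle and diameter, and number of bolls. The cloud must be
#' labeled and in meters (denormalized). Deterministic given the cloud.
#'
#' @param cloud a labeled [plant_cloud()] in meters.
#' @param stem_slice slice height in meters for stem/branch diameter fits.
#' @param branch_eps,branch_min_cluster,attach_radius,attach_avg_radius,angle_radius,cluster_min_pts
#'   branch detection parameters, see [detect_branches()].
#' @param node_tol same-node tolerance in meters.
#' @param boll_eps,boll_min_pts,boll_min_height,iqr_mult boll counting
#'   parameters, see [count_bolls()].
#' @return A `plant_traits` object: scalars `stem_height`, `stem_diameter`,
#'   `n_branches`, `n_nodes`, `n_bolls`; `branches` (data.frame with
#'   `attach_x/y/z`, `min_z`, `inclination_deg`, `diameter`); `node_locations`;
#'   and the boll cluster table.
#' @export
extract_all <- function(cloud,
                        stem_slice = 0.01,
                        branch_eps = 0.02, branch_min_cluster = 100L,
                        attach_radius = 0.02, attach_avg_radius = 0.01,
                        angle_radius = 0.06, cluster_min_pts = 10L,
                        node_tol = 0.01,
                        boll_eps = 0.005, boll_min_pts = 100L,
                        boll_min_height = 0.03, iqr_mult = 1.5) {
  require_labels(cloud)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("trait extraction failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  height <- stage("stem_height", stem_height(cloud))
  diameter <- stage("stem_diameter", stem_diameter(cloud, stem_slice))
  bolls <- stage("count_bolls",
                 count_bolls(cloud, boll_eps, boll_min_pts, boll_min_height,
                             iqr_mult))
  branches <- stage("detect_branches",
                    detect_branches(cloud, branch_eps, branch_min_cluster,
                                    attach_radius, attach_avg_radius,
                                    angle_radius, cluster_min_pts,
                                    boll_cutoff = TRUE, boll_eps,
                                    boll_min_pts, boll_min_height))
  angles <- stage("branch_inclination",
                  vapply(branches, branch_inclination, 0))
  diams <- stage("branch_diameter",
                 vapply(branches, branch_diameter, 0, slice_height = stem_slice))
  nodes <- stage("detect_nodes", detect_nodes(branches, cloud, node_tol,
                                              stem_slice))
  att <- if (length(branches))
    t(vapply(branches, `[[`, numeric(3), "attachment")) else
      matrix(numeric(0), 0, 3)
  branch_tab <- data.frame(
    attach_x = att[, 1], attach_y = att[, 2], attach_z = att[, 3],
    min_z = vapply(branches, `[[`, 0, "min_z"),
    inclination_deg = angles, diameter = diams,
    node = nodes$node_of
  )
  structure(list(
    stem_height = height,
    stem_diameter = diameter,
    n_branches = length(branches),
    n_nodes = nodes$n_nodes,
    n_bolls = bolls$n_bolls,
    branches = branch_tab,
    node_locations = nodes$node_locations,
    boll_clusters = bolls$clusters,
    records = branches
  ), class = "plant_traits")
}

#' @export
print.plant_traits <- function(x, ...) {
  cat("<plant_traits>\n")
  cat(sprintf("  main stem:  height %.3f m, diameter %.1f mm\n",
              x$stem_height, 1000 * x$stem_diameter))
  cat(sprintf("  branches:   %d (nodes: %d)\n", x$n_branches, x$n_nodes))
  if (x$n_branches > 0)
    cat(sprintf("    inclination %.1f-%.1f deg, diameter %.1f-%.1f mm\n",
                min(x$branches$inclination_deg), max(x$branches$inclination_deg),
                1000 * min(x$branches$diameter), 1000 * max(x$branches$diameter)))
  cat(sprintf("  bolls:      %d\n", x$n_bolls))
  invisible(x)
}

#' Flatten traits to a one-row data.frame
#'
#' Per-branch angle and diameter are summarized by their means, giving the
#' seven per-plant trait values used for cohort tables and validation.
#'
#' @param traits a `plant_traits` or `ground_truth` object.
#' @return A one-row data.frame with columns `stem_height`, `stem_diameter`,
#'   `n_branches`, `n_nodes`, `n_bolls`, `branch_angle`, `branch_diameter`.
#' @export
traits_row <- function(traits) {
  if (inherits(traits, "plant_traits")) {
    data.frame(stem_height = traits$stem_height,
               stem_diameter = traits$stem_diameter,
               n_branches = traits$n_branches,
               n_nodes = traits$n_nodes,
               n_bolls = traits$n_bolls,
               branch_angle = if (traits$n_branches)
                 mean(traits$branches$inclination_deg) else NA_real_,
               branch_diameter = if (traits$n_branches)
                 mean(traits$branches$diameter) else NA_real_)
  } else if (inherits(traits, "ground_truth")) {
    data.frame(stem_height = traits$stem_height,
               stem_diameter = traits$stem_diameter,
               n_branches = traits$n_branches,
               n_nodes = traits$n_nodes,
               n_bolls = traits$n_bolls,
               branch_angle = if (traits$n_branches)
                 mean(traits$branch_angles) else NA_real_,
               branch_diameter = if (traits$n_branches)
                 mean(traits$branch_diameters) else NA_real_)
  } else stop("unsupported traits object")
}
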