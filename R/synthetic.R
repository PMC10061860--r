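#' Specification of a synthetic cotton plant
#'
#' Describes a defoliated cotton plant as surfaces: a tubular main stem
#' (straight, curved, or tilted), tubular branches attached at nodes along the
#' stem, and near-spherical bolls placed along the outer part of branches.
#' [generate_plant()] samples points on these surfaces at LiDAR-like density.
#'
#' Fields left `NULL` are drawn at generation time from the plant's seed:
#' node heights are spaced along the stem with at least 3 cm between distinct
#' nodes, branch inclinations are drawn in 18-38 degrees, branch azimuths
#' follow a 137.5 degree spiral, and branch diameters are drawn in 7-10 mm.
#'
#' @param stem_height stem z-span in meters (the main stem trait).
#' @param stem_diameter stem diameter in meters at the base.
#' @param stem_shape `"straight"`, `"curved"` (quadratic bow, vertical at the
#'   base), or `"tilted"` (straight but leaning).
#' @param shape_magnitude horizontal offset in meters of the stem top relative
#'   to its base (ignored for `"straight"`).
#' @param n_branches number of branches.
#' @param node_heights optional numeric vector of branch attachment heights in
#'   meters, strictly inside `(0, stem_height)`.
#' @param branch_angles optional inclinations in degrees in `[0, 90)`
#'   (0 = horizontal).
#' @param branch_lengths optional branch lengths in meters.
#' @param branch_diameters optional branch diameters in meters.
#' @param n_bolls number of bolls (includes bolls of connected pairs).
#' @param boll_radius boll radius in meters; at least 0.015 so that a boll's
#'   height exceeds the 3 cm counting filter.
#' @param boll_gap surface-to-surface gap in meters between bolls on the same
#'   branch (> 5 mm keeps them separable by the counting rule).
#' @param connected_boll_pairs number of boll pairs placed so close (center
#'   separation of one radius) that they fuse into a single cluster,
#'   exercising the outlier-cluster counting rule.
#' @param same_node_pairs number of branch pairs attached 8 mm apart in z
#'   (within the 1 cm node rule) on opposite sides of the stem, so they share
#'   a node.
#' @param attachment_gap radial gap in meters between the stem surface and the
#'   start of a branch tube, emulating the occlusion gap a scanner leaves at
#'   junctions.
#' @param surface_density surface sampling density in points per cm^2.
#' @param jitter_sigma standard deviation in meters of isotropic Gaussian
#'   noise added to every point.
#' @param seed integer seed controlling all randomness of the plant.
#'
#' @return A `plant_spec` object (a validated list).
#' @export
#' @examples
#' sp <- plant_spec(stem_height = 0.8, n_branches = 4L, n_bolls = 6L, seed = 7)
#' pl <- generate_plant(sp)
#' pl$truth
plant_spec <- function(stem_height = 1.0,
                       stem_diameter = 0.016,
                       stem_shape = c("straight", "curved", "tilted"),
                       shape_magnitude = 0.05,
                       n_branches = 8L,
                       node_heights = NULL,
                       branch_angles = NULL,
                       branch_lengths = NULL,
                       branch_diameters = NULL,
                       n_bolls = 10L,
                       boll_radius = 0.02,
                       boll_gap = 0.01,
                       connected_boll_pairs = 0L,
                       same_node_pairs = 0L,
                       attachment_gap = 0.014,
                       surface_density = 160,
                       jitter_sigma = 5e-4,
                       seed = 1L) {
  stem_shape <- match.arg(stem_shape)
  spec <- list(stem_height = stem_height, stem_diameter = stem_diameter,
               stem_shape = stem_shape, shape_magnitude = shape_magnitude,
               n_branches = as.integer(n_branches), node_heights = node_heights,
               branch_angles = branch_angles, branch_lengths = branch_lengths,
               branch_diameters = branch_diameters, n_bolls = as.integer(n_bolls),
               boll_radius = boll_radius, boll_gap = boll_gap,
               connected_boll_pairs = as.integer(connected_boll_pairs),
               same_node_pairs = as.integer(same_node_pairs),
               attachment_gap = attachment_gap,
               surface_density = surface_density, jitter_sigma = jitter_sigma,
               seed = as.integer(seed))
  validate_spec(spec)
  structure(spec, class = "plant_spec")
}

validate_spec <- function(s) {
  if (s$stem_height <= 0 || s$stem_diameter <= 0)
    stop("stem dimensions must be positive")
  if (s$n_branches < 0 || s$n_bolls < 0)
    stop("counts must be non-negative")
  if (s$n_bolls > 0 && s$boll_radius < 0.015)
    stop("boll_radius must be >= 0.015 m so bolls pass the 3 cm height filter")
  if (!is.null(s$node_heights)) {
    if (length(s$node_heights) != s$n_branches)
      stop("node_heights must have one entry per branch")
    if (any(s$node_heights <= 0 | s$node_heights >= s$stem_height))
      stop("node_heights must lie strictly inside (0, stem_height)")
  }
  if (!is.null(s$branch_angles) &&
      any(s$branch_angles < 0 | s$branch_angles >= 90))
    stop("branch_angles must lie in [0, 90) degrees")
  if (s$same_node_pairs > max(0L, s$n_branches - 1L))
    stop("too many same-node pairs for the number of branches")
  if (s$connected_boll_pairs * 2L > s$n_bolls)
    stop("too many connected pairs for the number of bolls")
  if (s$surface_density <= 0 || s$jitter_sigma < 0)
    stop("surface_density must be positive and jitter_sigma non-negative")
  invisible(s)
}

# horizontal offset of the stem axis at height z (two columns of coefficients)
stem_axis_xy <- function(z, spec, azim) {
  H <- spec$stem_height
  off <- switch(spec$stem_shape,
                straight = rep(0, length(z)),
                tilted = spec$shape_magnitude * z / H,
                curved = spec$shape_magnitude * (z / H)^2)
  cbind(off * cos(azim), off * sin(azim))
}

# unit tangent of the stem axis at height z
stem_axis_tangent <- function(z, spec, azim) {
  H <- spec$stem_height
  slope <- switch(spec$stem_shape,
                  straight = rep(0, length(z)),
                  tilted = rep(spec$shape_magnitude / H, length(z)),
                  curved = 2 * spec$shape_magnitude * z / H^2)
  t <- cbind(slope * cos(azim), slope * sin(azim), rep(1, length(z)))
  t / sqrt(rowSums(t^2))
}

# sample n points on a tube of radius r around centerline p(s) = p0 + dir * s
sample_tube <- function(p0, dir, s_min, s_max, r, n) {
  s <- runif(n, s_min, s_max)
  phi <- runif(n, 0, 2 * pi)
  e1 <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- e1 - sum(e1 * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
          dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  ctr <- matrix(p0, n, 3, byrow = TRUE) + outer(s, dir)
  ctr + r * (outer(cos(phi), e1) + outer(sin(phi), e2))
}

sample_sphere <- function(center, r, n) {
  g <- matrix(stats::rnorm(3 * n), n, 3)
  g <- g / sqrt(rowSums(g^2))
  sweep(g * r, 2, center, `+`)
}

n_for_area <- function(area_m2, density_cm2) {
  max(1L, as.integer(round(area_m2 * 1e4 * density_cm2)))
}

#' Generate a labeled synthetic cotton plant
#'
#' Samples points on the surfaces described by a [plant_spec()] (stem and
#' branch tubes, boll spheres), applies Gaussian jitter, and returns the
#' labeled cloud together with a ground-truth trait record consistent with the
#' realized geometry. Byte-identical output for identical specs.
#'
#' @param spec a [plant_spec()].
#' @return A list with `cloud` (a [plant_cloud()], labels 0/1/2) and `truth`
#'   (a `ground_truth` list: `stem_height`, `stem_diameter`, `n_branches`,
#'   `n_nodes`, `branch_angles`, `branch_diameters`, `attachment_heights`,
#'   `n_bolls`).
#' @export
generate_plant <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  validate_spec(spec)
  with_seed(spec$seed, generate_plant_impl(spec))
}

generate_plant_impl <- function(spec) {
  H <- spec$stem_height
  r_s <- spec$stem_diameter / 2
  B <- spec$n_branches
  stem_azim <- runif(1, 0, 2 * pi)

  # --- realize branch layout -------------------------------------------------
  n_main <- B - spec$same_node_pairs          # branches that own a node
  if (is.null(spec$node_heights)) {
    if (B > 0) {
      lo <- 0.22 * H
      hi <- 0.88 * H
      base <- if (n_main > 1) seq(lo, hi, length.out = n_main) else (lo + hi) / 2
      base <- base + runif(n_main, -0.002, 0.002)
      # partner branches share a node: attached 8 mm above their host
      node_z <- c(base, base[seq_len(spec$same_node_pairs)] + 0.008)
    } else node_z <- numeric(0)
  } else node_z <- spec$node_heights

  # plant-level bases with per-branch scatter: architecture varies more
  # between plants (genotype, vigor) than within one
  angles <- spec$branch_angles %||% {
    a <- pmin(42, pmax(15, runif(1, 20, 34) + runif(n_main, -6, 6)))
    c(a, a[seq_len(spec$same_node_pairs)])   # partners share the inclination
  }
  if (length(angles) != B) stop("branch_angles must have one entry per branch")
  diam_b <- spec$branch_diameters %||%
    pmax(0.005, runif(1, 0.006, 0.011) + runif(B, -8e-4, 8e-4))
  if (length(diam_b) == 1) diam_b <- rep(diam_b, B)
  azim <- stem_azim + (seq_len(B) - 1) * 137.5 * pi / 180
  if (spec$same_node_pairs > 0) {
    pidx <- n_main + seq_len(spec$same_node_pairs)
    azim[pidx] <- azim[seq_len(spec$same_node_pairs)] + pi
  }

  # --- allocate bolls to branches, topmost branch first ----------------------
  nb <- spec$n_bolls
  boll_count <- integer(B)
  if (B > 0 && nb > 0) {
    ord <- order(node_z, decreasing = TRUE)
    boll_count[ord] <- tabulate((seq_len(nb) - 1L) %% B + 1L, nbins = B)
  }

  # --- branch lengths: long enough for the trait region and the bolls --------
  r_boll <- spec$boll_radius
  d_c <- 2 * r_boll + spec$boll_gap              # center spacing on a branch
  theta <- angles * pi / 180
  s0 <- (r_s + spec$attachment_gap + diam_b / 2) / cos(theta)
  need <- s0 + 0.08 / cos(theta) +
    pmax(0, boll_count - 1) * d_c + 2 * r_boll + 0.02
  lengths <- pmax(spec$branch_lengths %||% runif(B, 0.20, 0.32), need)
  if (any(lengths > 1.5))
    stop("geometrically impossible spec: branches longer than 1.5 m needed ",
         "to host the requested bolls")

  dens <- spec$surface_density
  coords <- vector("list", 2 + B)
  labels <- vector("list", 2 + B)

  # --- stem ------------------------------------------------------------------
  n_stem <- n_for_area(2 * pi * r_s * H, dens)
  zs <- runif(n_stem, 0, H)
  ctr <- cbind(stem_axis_xy(zs, spec, stem_azim), zs)
  tang <- stem_axis_tangent(zs, spec, stem_azim)
  # frame orthogonal to the local tangent (tangent is never near the x axis)
  e1 <- cbind(1 - tang[, 1]^2, -tang[, 2] * tang[, 1], -tang[, 3] * tang[, 1])
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(tang[, 2] * e1[, 3] - tang[, 3] * e1[, 2],
              tang[, 3] * e1[, 1] - tang[, 1] * e1[, 3],
              tang[, 1] * e1[, 2] - tang[, 2] * e1[, 1])
  phi <- runif(n_stem, 0, 2 * pi)
  coords[[1]] <- ctr + r_s * (e1 * cos(phi) + e2 * sin(phi))
  labels[[1]] <- rep(LABEL_STEM, n_stem)

  # --- branches and their bolls ----------------------------------------------
  boll_xyz <- list()
  for (i in seq_len(B)) {
    dir <- c(cos(theta[i]) * cos(azim[i]), cos(theta[i]) * sin(azim[i]),
             sin(theta[i]))
    attach <- c(stem_axis_xy(node_z[i], spec, stem_azim), node_z[i])
    r_b <- diam_b[i] / 2
    n_br <- n_for_area(2 * pi * r_b * (lengths[i] - s0[i]), dens)
    coords[[1 + i]] <- sample_tube(attach, dir, s0[i], lengths[i], r_b, n_br)
    labels[[1 + i]] <- rep(LABEL_BRANCH, n_br)
    if (boll_count[i] > 0) {
      s_c <- lengths[i] - (seq_len(boll_count[i]) - 1) * d_c
      for (s in s_c)
        boll_xyz[[length(boll_xyz) + 1]] <- attach + dir * s
    }
  }

  # --- connected boll pairs: move one boll next to another -------------------
  # (the pair is two overlapping spheres one radius apart; it fuses into a
  # single cluster under the 5 mm counting rule)
  n_pairs <- spec$connected_boll_pairs
  if (n_pairs > 0) {
    if (length(boll_xyz) < 2 * n_pairs) stop("not enough bolls for pairs")
    for (p in seq_len(n_pairs)) {
      host <- boll_xyz[[2 * p - 1]]
      offs <- c(cos(stem_azim + p), sin(stem_azim + p), 0)
      boll_xyz[[2 * p]] <- host + offs * r_boll
    }
  }
  n_per_boll <- n_for_area(4 * pi * r_boll^2, dens)
  for (bc in boll_xyz) {
    coords[[length(coords) + 1]] <- sample_sphere(bc, r_boll, n_per_boll)
    labels[[length(labels) + 1]] <- rep(LABEL_BOLL, n_per_boll)
  }

  xyz <- do.call(rbind, coords[!vapply(coords, is.null, TRUE)])
  lab <- unlist(labels[!vapply(labels, is.null, TRUE)])
  if (spec$jitter_sigma > 0)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$jitter_sigma),
                        nrow(xyz), 3)
  cloud <- plant_cloud(xyz, labels = as.integer(lab))

  stem_z <- xyz[lab == LABEL_STEM, 3]
  truth <- structure(list(
    stem_height = max(stem_z) - min(stem_z),
    stem_diameter = spec$stem_diameter,
    n_branches = B,
    n_nodes = count_nodes_by_rule(node_z),
    branch_angles = angles,
    branch_diameters = diam_b,
    attachment_heights = node_z,
    n_bolls = length(boll_xyz)
  ), class = "ground_truth")
  list(cloud = cloud, truth = truth)
}

# walk attachment heights in ascending order; heights within 1 cm of the
# previous one share a node (the field convention used for node counting)
count_nodes_by_rule <- function(z, tol = 0.01) {
  if (length(z) == 0) return(0L)
  z <- sort(z)
  sum(c(TRUE, diff(z) > tol))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth> stem %.3f m x %.1f mm | %d branches, ",
                     "%d nodes | %d bolls\n"),
              x$stem_height, 1000 * x$stem_diameter, x$n_branches, x$n_nodes,
              x$n_bolls))
  if (x$n_branches > 0)
    cat(sprintf("  branch angles %.1f-%.1f deg, diameters %.1f-%.1f mm\n",
                min(x$branch_angles), max(x$branch_angles),
                1000 * min(x$branch_diameters), 1000 * max(x$branch_diameters)))
  invisible(x)
}

#' Inject segmentation-like label errors
#'
#' Emulates the error modes of a part-segmentation network. `boundary_swap`
#' flips each point lying within `region_size` of a part boundary to the label
#' of the nearest other-part point, independently with probability `fraction`.
#' `region_flip` relabels one contiguous blob - all points of the source label
#' inside a ball of radius `region_size` centered on a random source-label
#' point - from main stem to branch or vice versa. Coordinates are never
#' modified.
#'
#' @param cloud a labeled [plant_cloud()].
#' @param mode `"boundary_swap"` or `"region_flip"`.
#' @param fraction flip probability for boundary points (boundary_swap only).
#' @param region_size boundary distance, or blob radius, in meters.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param from source label for `region_flip`: `"main_stem"`, `"branch"`, or
#'   `"any"` (pick either at random).
#' @param center optional blob center (3-vector) for `region_flip`; default is
#'   a random point of the source label.
#' @return The perturbed [plant_cloud()].
#' @export
perturb_labels <- function(cloud, mode = c("boundary_swap", "region_flip"),
                           fraction = 0.02, region_size = 0.01, seed = NULL,
                           from = c("any", "main_stem", "branch"),
                           center = NULL) {
  require_labels(cloud)
  mode <- match.arg(mode)
  from <- match.arg(from)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  with_seed(seed, {
    if (mode == "boundary_swap") perturb_boundary(cloud, fraction, region_size)
    else perturb_region(cloud, region_size, from, center)
  })
}

perturb_boundary <- function(cloud, fraction, region_size) {
  labels <- cloud$labels
  classes <- c(LABEL_STEM, LABEL_BRANCH, LABEL_BOLL)
  present <- classes[classes %in% labels]
  if (length(present) < 2 || fraction == 0) return(cloud)
  n <- n_points(cloud)
  best_d <- rep(Inf, n)
  best_lab <- labels
  for (cl in present) {
    sel <- labels == cl
    other <- cloud$coords[sel, , drop = FALSE]
    qry <- which(!sel & labels %in% present)
    if (!length(qry)) next
    d <- nn_dist_to_set(cloud$coords[qry, , drop = FALSE], other,
                        cap = 2 * region_size)
    upd <- d < best_d[qry]
    best_d[qry[upd]] <- d[upd]
    best_lab[qry[upd]] <- cl
  }
  boundary <- which(best_d <= region_size)
  flip <- boundary[runif(length(boundary)) < fraction]
  labels[flip] <- best_lab[flip]
  cloud$labels <- labels
  cloud
}

perturb_region <- function(cloud, region_size, from, center) {
  labels <- cloud$labels
  src <- switch(from,
                main_stem = LABEL_STEM,
                branch = LABEL_BRANCH,
                any = sample(c(LABEL_STEM, LABEL_BRANCH), 1))
  cand <- which(labels == src)
  if (!length(cand)) return(cloud)
  if (is.null(center))
    center <- cloud$coords[cand[sample.int(length(cand), 1)], ]
  d2 <- rowSums(sweep(cloud$coords, 2, center)^2)
  blob <- d2 <= region_size^2 & labels == src
  labels[blob] <- if (src == LABEL_STEM) LABEL_BRANCH else LABEL_STEM
  cloud$labels <- labels
  cloud
}

#' Append far-outlier noise points
#'
#' Adds `n_outliers` points uniformly distributed over a thin spherical shell
#' of the given radius around the cloud's bounding-sphere center, labeled
#' unlabeled (-1). Used to exercise [sor_denoise()].
#'
#' @param cloud a [plant_cloud()].
#' @param n_outliers number of points to append.
#' @param radius shell radius in meters (points land in 0.95-1.05 x radius).
#' @param seed integer seed, or `NULL`.
#' @return The augmented [plant_cloud()].
#' @export
add_outlier_noise <- function(cloud, n_outliers, radius, seed = NULL) {
  stopifnot(inherits(cloud, "plant_cloud"))
  if (n_outliers == 0) return(cloud)
  with_seed(seed, {
    center <- colMeans(cloud$coords)
    g <- matrix(stats::rnorm(3 * n_outliers), n_outliers, 3)
    g <- g / sqrt(rowSums(g^2))
    r <- radius * runif(n_outliers, 0.95, 1.05)
    pts <- sweep(g * r, 2, center, `+`)
    labels <- if (!is.null(cloud$labels))
      c(cloud$labels, rep(LABEL_NONE, n_outliers))
    colors <- if (!is.null(cloud$colors))
      rbind(cloud$colors, matrix(128L, n_outliers, 3))
    plant_cloud(rbind(cloud$coords, pts), colors = colors, labels = labels)
  })
}
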