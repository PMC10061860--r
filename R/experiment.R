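#' Simulated parameter-recovery experiment
#'
#' Generates a cohort of synthetic plants spanning realistic cotton
#' architectures (stem heights 0.5-1.5 m across straight, curved, and tilted
#' stems; 4-12 branches; 5-40 bolls; every fourth plant carries a same-node
#' branch pair), optionally injects segmentation-like label errors (boundary
#' swaps at 2% plus one 2 cm stem-corridor region flip per plant), applies
#' slice-wise label correction to the perturbed labels, extracts the seven
#' architectural traits, and tabulates estimates against the generator ground
#' truth. This is the package's core validation harness.
#'
#' @param n_plants number of plants in the cohort.
#' @param seed integer seed for the whole experiment.
#' @param perturb inject label errors (and correct them) before extraction;
#'   when `FALSE` traits are extracted from the clean labels.
#' @param swap_fraction boundary-swap flip probability.
#' @param flip_radius stem-corridor region-flip radius in meters.
#' @param correct apply [correct_stem_branch()] before extraction (only
#'   meaningful with `perturb = TRUE`).
#' @param keep_iou also record the main-stem IoU against the clean labels
#'   before and after correction (perturbed runs only).
#' @return A list with `truth` and `est` (one data.frame row per plant, see
#'   [traits_row()]), and, for perturbed runs with `keep_iou`, `stem_iou_pre`
#'   and `stem_iou_post` vectors.
#' @export
run_recovery_experiment <- function(n_plants = 20L, seed = 1L,
                                    perturb = TRUE, swap_fraction = 0.02,
                                    flip_radius = 0.02, correct = perturb,
                                    keep_iou = perturb) {
  specs <- with_seed(seed, cohort_specs(n_plants, seed))
  truth <- est <- vector("list", n_plants)
  iou_pre <- iou_post <- rep(NA_real_, n_plants)
  for (i in seq_len(n_plants)) {
    pl <- generate_plant(specs[[i]])
    cloud <- pl$cloud
    clean_labels <- cloud$labels
    if (perturb) {
      cloud <- perturb_labels(cloud, "boundary_swap", fraction = swap_fraction,
                              region_size = 0.01, seed = specs[[i]]$seed + 1L)
      # one region flip confined to the corridor interior: the corrector
      # anchors on the bottom stem slice and stops at the topmost stem slice,
      # so blobs that truncate either end are outside its contract
      cloud <- perturb_labels(cloud, "region_flip", region_size = flip_radius,
                              from = "main_stem",
                              center = corridor_point(cloud, 0.05,
                                                      specs[[i]]$seed + 2L),
                              seed = specs[[i]]$seed + 2L)
      if (keep_iou)
        iou_pre[i] <- stem_iou(cloud$labels, clean_labels)
    }
    if (perturb && correct) {
      cloud <- correct_stem_branch(cloud)
      if (keep_iou)
        iou_post[i] <- stem_iou(cloud$labels, clean_labels)
    }
    truth[[i]] <- traits_row(pl$truth)
    est[[i]] <- traits_row(extract_all(cloud))
  }
  out <- list(truth = do.call(rbind, truth), est = do.call(rbind, est))
  if (perturb && keep_iou) {
    out$stem_iou_pre <- iou_pre
    out$stem_iou_post <- iou_post
  }
  out
}

# draw the cohort's plant specifications (call under with_seed)
cohort_specs <- function(n_plants, seed) {
  shapes <- c("straight", "curved", "tilted")
  lapply(seq_len(n_plants), function(i) {
    nb <- sample(4:12, 1)
    plant_spec(
      stem_height = runif(1, 0.5, 1.5),
      stem_diameter = runif(1, 0.012, 0.024),
      stem_shape = shapes[(i - 1L) %% 3L + 1L],
      shape_magnitude = runif(1, 0.03, 0.10),
      n_branches = nb,
      n_bolls = sample(5:40, 1),
      boll_radius = runif(1, 0.016, 0.025),
      same_node_pairs = if (i %% 4L == 0L && nb >= 5L) 1L else 0L,
      seed = seed * 1000L + i
    )
  })
}

# a random main-stem point at least `buffer` meters from both stem ends
corridor_point <- function(cloud, buffer, seed) {
  idx <- which(cloud$labels == LABEL_STEM)
  z <- cloud$coords[idx, 3]
  eligible <- idx[z >= min(z) + buffer & z <= max(z) - buffer]
  if (!length(eligible)) eligible <- idx
  cloud$coords[with_seed(seed, sample(eligible, 1)), ]
}

stem_iou <- function(pred, truth) {
  p <- pred == LABEL_STEM
  t <- truth == LABEL_STEM
  sum(p & t) / sum(p | t)
}

#' Simulated boll-counting experiment
#'
#' Generates plants whose boll counts span 5-40, a subset of which contain one
#' connected boll pair (two bolls one radius apart, fusing into a single
#' cluster), applies boundary-swap label noise, and counts bolls with
#' [count_bolls()] under the standard parameters.
#'
#' @param n_plants number of plants.
#' @param seed integer seed.
#' @param n_connected how many plants carry one connected boll pair.
#' @param swap_fraction boundary-swap flip probability.
#' @return A data.frame with columns `true` and `est` boll counts per plant.
#' @export
run_boll_count_experiment <- function(n_plants = 20L, seed = 1L,
                                      n_connected = 5L,
                                      swap_fraction = 0.02) {
  specs <- with_seed(seed + 1L, {
    lapply(seq_len(n_plants), function(i) {
      plant_spec(
        stem_height = runif(1, 0.6, 1.3),
        stem_diameter = runif(1, 0.012, 0.024),
        n_branches = sample(5:10, 1),
        n_bolls = sample(5:40, 1),
        boll_radius = runif(1, 0.016, 0.025),
        connected_boll_pairs = if (i <= n_connected) 1L else 0L,
        seed = seed * 1000L + 500L + i
      )
    })
  })
  res <- lapply(seq_along(specs), function(i) {
    pl <- generate_plant(specs[[i]])
    cloud <- perturb_labels(pl$cloud, "boundary_swap",
                            fraction = swap_fraction, region_size = 0.01,
                            seed = specs[[i]]$seed + 1L)
    data.frame(true = pl$truth$n_bolls, est = count_bolls(cloud)$n_bolls)
  })
  do.call(rbind, res)
}

#' Per-trait error summary of a recovery experiment
#'
#' Mean absolute percentage error and cross-plant coefficient of
#' determination (ordinary least squares of estimate on truth) for each of
#' the seven traits.
#'
#' @param truth,est data.frames as returned by [run_recovery_experiment()].
#' @return A data.frame with columns `trait`, `mape` (percent), `r2`.
#' @export
trait_error_summary <- function(truth, est) {
  traits <- names(truth)
  do.call(rbind, lapply(traits, function(tr) {
    g <- truth[[tr]]
    e <- est[[tr]]
    data.frame(trait = tr,
               mape = 100 * mean(abs(e - g) / abs(g)),
               r2 = r_squared(e, g))
  }))
}

r_squared <- function(est, truth) {
  if (all(est == truth)) return(1)
  summary(stats::lm(est ~ truth))$r.squared
}
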