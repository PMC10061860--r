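#' Pipeline configuration
#'
#' All stage parameters of the processing workflow, with the standard
#' defaults: SOR denoising with 6 neighbors and 1 standard deviation,
#' down-sampling to 100,000 points, 1 cm slices with correction margins
#' 1.0 and 1.2 cm, branch clustering at eps 2 cm / minPoints 100 with a 2 cm
#' attachment radius and 6 cm angle radius, boll clustering at eps 5 mm /
#' minPoints 100 with a 3 cm height filter and the 1.5 IQR outlier rule.
#'
#' @param ... named overrides of the defaults listed above.
#' @return A `pipeline_config` object (a validated named list).
#' @export
#' @examples
#' pipeline_config(denoise = FALSE, seed = 42)
pipeline_config <- function(...) {
  cfg <- list(
    denoise = TRUE, denoise_k = 6L, denoise_std = 1.0,
    downsample = TRUE, target_points = 100000L,
    normalize = TRUE,
    correct = TRUE, slice_height = 0.01, margins = c(0.010, 0.012),
    branch_eps = 0.02, branch_min_cluster = 100L,
    attach_radius = 0.02, attach_avg_radius = 0.01, angle_radius = 0.06,
    cluster_min_pts = 10L, node_tol = 0.01,
    boll_eps = 0.005, boll_min_pts = 100L, boll_min_height = 0.03,
    iqr_mult = 1.5,
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  numeric_fields <- setdiff(names(cfg), c("denoise", "downsample", "normalize",
                                          "correct"))
  for (f in numeric_fields)
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] <= 0 & f != "seed"))
      stop("config field must be positive: ", f)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config`: the path, invisibly;
#'   `read_pipeline_config`: a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for config files")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for config files")
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full processing workflow on one labeled cloud
#'
#' Preprocess (denoise, normalize, down-sample), map back to meters, apply
#' slice-wise stem/branch label correction, and extract the seven
#' architectural traits. Semantic segmentation itself is an interface, not a
#' stage: part labels must already be present in the input (from an
#' annotation tool or a segmentation model). When `truth_labels` is supplied,
#' the corrected labeling is also scored against it.
#'
#' @param input a [plant_cloud()] or a file path readable by [read_cloud()].
#' @param config a [pipeline_config()].
#' @param truth_labels optional reference labels (aligned with the input
#'   cloud; only usable when down-sampling and denoising are disabled or the
#'   input already fits the target size).
#' @return A list with `traits` (a `plant_traits`), `cloud` (the corrected
#'   [plant_cloud()]), `report` (a `seg_report` or `NULL`), and `log`
#'   (per-stage point counts and timings in seconds).
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         truth_labels = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cloud <- if (inherits(input, "plant_cloud")) input else read_cloud(input)
  log <- list()
  tick <- function(name, n) {
    log[[name]] <<- list(points = n, at = as.numeric(Sys.time()))
  }
  t0 <- Sys.time()
  tick("input", n_points(cloud))

  if (isTRUE(config$denoise)) {
    cloud <- sor_denoise(cloud, config$denoise_k, config$denoise_std)$cloud
    tick("denoise", n_points(cloud))
  }
  if (isTRUE(config$normalize)) {
    norm <- normalize_cloud(cloud)
    cloud <- norm$cloud
    tick("normalize", n_points(cloud))
  }
  if (isTRUE(config$downsample)) {
    cloud <- random_downsample(cloud, config$target_points, seed = config$seed)
    tick("downsample", n_points(cloud))
  }
  # segmentation would run here on the normalized cloud; labels are supplied
  if (isTRUE(config$normalize)) {
    cloud <- denormalize_cloud(cloud, norm$state)
    tick("denormalize", n_points(cloud))
  }
  require_labels(cloud)
  if (isTRUE(config$correct)) {
    cloud <- correct_stem_branch(cloud, config$slice_height, config$margins)
    tick("correct", n_points(cloud))
  }
  traits <- extract_all(cloud,
                        stem_slice = config$slice_height,
                        branch_eps = config$branch_eps,
                        branch_min_cluster = config$branch_min_cluster,
                        attach_radius = config$attach_radius,
                        attach_avg_radius = config$attach_avg_radius,
                        angle_radius = config$angle_radius,
                        cluster_min_pts = config$cluster_min_pts,
                        node_tol = config$node_tol,
                        boll_eps = config$boll_eps,
                        boll_min_pts = config$boll_min_pts,
                        boll_min_height = config$boll_min_height,
                        iqr_mult = config$iqr_mult)
  tick("traits", n_points(cloud))

  report <- NULL
  if (!is.null(truth_labels)) {
    if (length(truth_labels) != n_points(cloud))
      stop("truth_labels do not align with the processed cloud; disable ",
           "denoising/down-sampling to score against reference labels")
    report <- evaluate_segmentation(cloud$labels, truth_labels)
  }
  log$total_seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(traits = traits, cloud = cloud, report = report, log = log)
}
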