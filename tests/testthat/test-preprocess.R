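test_that("SOR removes a far outlier from a regular grid and nothing else", {
  pc <- grid_cloud(spacing = 0.01, extra = c(1, 1, 1))
  res <- sor_denoise(pc, k = 6L, std_mult = 1.0)
  expect_equal(res$removed, 28L)
  expect_equal(n_points(res$cloud), 27L)
  # conservation
  expect_equal(n_points(res$cloud) + length(res$removed), n_points(pc))
  # unattainable threshold removes nothing
  expect_length(sor_denoise(pc, std_mult = 1e6)$removed, 0)
})

test_that("SOR matches the exhaustive distance-matrix oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(100:500, 1)
    coords <- matrix(rnorm(3 * n, sd = 0.05), n, 3)
    coords[sample(n, 5), ] <- matrix(runif(15, 0.5, 1), 5, 3)  # outliers
    pc <- plant_cloud(coords)
    expect_equal(sor_denoise(pc)$removed, brute_sor_removed(coords))
  }
})

test_that("SOR requires more points than k", {
  expect_error(sor_denoise(plant_cloud(diag(3)), k = 6L), "more than k")
})

test_that("normalization centers the cloud and scales its radius to one", {
  res <- normalize_cloud(plant_cloud(rbind(c(0, 0, 0), c(0, 0, 2))))
  expect_equal(res$cloud$coords, rbind(c(0, 0, -1), c(0, 0, 1)),
               ignore_attr = TRUE)
  expect_equal(res$state$centroid, c(x = 0, y = 0, z = 1))
  expect_equal(res$state$scale, 1)

  for (seed in 1:5) {
    set.seed(seed)
    pc <- plant_cloud(matrix(rnorm(300, sd = runif(1, 0.1, 10)), 100, 3))
    out <- normalize_cloud(pc)$cloud
    expect_equal(max(sqrt(rowSums(out$coords^2))), 1, tolerance = 1e-12)
  }
  expect_error(normalize_cloud(plant_cloud(matrix(1, 5, 3))), "degenerate")
})

test_that("an already-normalized cloud is a fixed point of normalization", {
  set.seed(1)
  pc <- normalize_cloud(plant_cloud(matrix(rnorm(300), 100, 3)))$cloud
  pc$coords <- sweep(pc$coords, 2, colMeans(pc$coords))  # recenter exactly
  pc$coords <- pc$coords / max(sqrt(rowSums(pc$coords^2)))
  out <- normalize_cloud(pc)$cloud
  expect_equal(out$coords, pc$coords, tolerance = 1e-9)
})

test_that("normalization is equivariant to scaling and translation", {
  set.seed(2)
  pc <- plant_cloud(matrix(rnorm(300), 100, 3))
  ref <- normalize_cloud(pc)$cloud$coords
  for (i in 1:3) {
    a <- runif(1, 0.1, 7)
    t <- rnorm(3, sd = 5)
    moved <- plant_cloud(sweep(pc$coords * a, 2, t, `+`))
    expect_equal(normalize_cloud(moved)$cloud$coords, ref, tolerance = 1e-9)
  }
})

test_that("denormalization inverts normalization exactly", {
  set.seed(3)
  pc <- plant_cloud(matrix(rnorm(600, sd = 2), 200, 3),
                    labels = sample(0:2, 200, replace = TRUE))
  res <- normalize_cloud(pc)
  back <- denormalize_cloud(res$cloud, res$state)
  expect_equal(back$coords, pc$coords, tolerance = 1e-9)
  expect_identical(back$labels, pc$labels)
  # geometry: unit-sphere cloud scaled by 0.7 around (1,2,3)
  st <- structure(list(centroid = c(1, 2, 3), scale = 0.7),
                  class = "norm_state")
  out <- denormalize_cloud(res$cloud, st)
  expect_lte(max(sqrt(rowSums(sweep(out$coords, 2, c(1, 2, 3))^2))), 0.7 + 1e-12)
})

test_that("normalization state survives its JSON sidecar", {
  st <- normalize_cloud(plant_cloud(matrix(rnorm(30), 10, 3)))$state
  f <- tempfile(fileext = ".json")
  write_norm_state(st, f)
  back <- read_norm_state(f)
  expect_equal(unname(back$centroid), unname(st$centroid), tolerance = 1e-12)
  expect_equal(back$scale, st$scale, tolerance = 1e-12)
})

test_that("random down-sampling is exact, reproducible, and label-balanced", {
  set.seed(4)
  n <- 100000L
  pc <- plant_cloud(matrix(runif(3 * n), n, 3),
                    labels = sample(0:2, n, replace = TRUE,
                                    prob = c(0.15, 0.15, 0.7)))
  small <- plant_cloud(diag(3))
  expect_identical(random_downsample(small, 100L), small)
  out <- random_downsample(pc, 10000L, seed = 9L)
  expect_equal(n_points(out), 10000L)
  out2 <- random_downsample(pc, 10000L, seed = 9L)
  expect_identical(out$coords, out2$coords)
  # class proportions preserved within 3 percentage points
  p_in <- table(pc$labels) / n
  p_out <- table(out$labels) / 10000
  expect_lt(max(abs(p_in - p_out)), 0.03)
  expect_error(random_downsample(pc, 0L), "n must be")
})
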