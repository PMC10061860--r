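test_that("stem height is the z-span of stem-labeled points only", {
  z <- seq(0.02, 1.02, length.out = 50)
  pc <- plant_cloud(cbind(0, 0, z), labels = rep(0L, 50))
  expect_equal(stem_height(pc), 1.0)
  # a mislabeled point above the stem top is excluded by the label filter
  pc2 <- plant_cloud(cbind(0, 0, c(z, max(z) + 0.05)),
                     labels = c(rep(0L, 50), 1L))
  expect_equal(stem_height(pc2), 1.0)
  expect_error(stem_height(plant_cloud(diag(3), labels = rep(1L, 3))),
               "main-stem")
})

test_that("a curved stem reports vertical height, not arc length", {
  pl <- generate_plant(plant_spec(stem_height = 1.0, stem_shape = "curved",
                                  shape_magnitude = 0.12, n_branches = 0L,
                                  n_bolls = 0L, seed = 13))
  expect_equal(stem_height(pl$cloud), 1.0, tolerance = 0.01)
})

test_that("Pratt circle fit is exact on noiseless circles", {
  f <- fit_circle_pratt(rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)))
  expect_equal(f$center, c(0, 0), tolerance = 1e-10)
  expect_equal(f$radius, 1, tolerance = 1e-10)
  # circumscribed circle of three points
  f2 <- fit_circle_pratt(rbind(c(0, 0), c(2, 0), c(1, 1)))
  expect_equal(f2$center, c(1, 0), tolerance = 1e-9)
  expect_equal(f2$radius, 1, tolerance = 1e-9)
  # shifted and scaled
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  f3 <- fit_circle_pratt(cbind(3 + 0.006 * cos(th), -2 + 0.006 * sin(th)))
  expect_equal(f3$center, c(3, -2), tolerance = 1e-9)
  expect_equal(f3$radius, 0.006, tolerance = 1e-9)
  expect_error(fit_circle_pratt(cbind(1:5, 2 * (1:5))), "degenerate")
  expect_error(fit_circle_pratt(rbind(c(0, 0), c(1, 1))), "3 points")
})

test_that("Pratt fit tracks the geometric least-squares fit on noisy rings", {
  for (seed in 1:3) {
    set.seed(seed)
    pts <- noisy_circle(40, r = 0.006, sigma = 3e-4)
    pratt <- fit_circle_pratt(pts)
    geo <- geo_circle_fit(pts)
    expect_equal(pratt$radius, 0.006, tolerance = 0.05)
    expect_equal(pratt$radius, geo$radius, tolerance = 0.01)
    expect_lt(sqrt(sum((pratt$center - geo$center)^2)), 0.01 * geo$radius)
  }
})

test_that("stem diameter comes from a circle fit on the bottom slice", {
  # exact cylinder of radius 5 mm
  tube <- make_tube(c(0, 0, 0), c(0, 0, 1), 0.3, 0.005, 2000)
  pc <- plant_cloud(tube, labels = rep(0L, 2000))
  expect_equal(stem_diameter(pc), 0.010, tolerance = 1e-9)
  # generated stem with jitter, true diameter 12 mm
  pl <- generate_plant(plant_spec(stem_height = 0.8, stem_diameter = 0.012,
                                  n_branches = 0L, n_bolls = 0L, seed = 14))
  expect_equal(stem_diameter(pl$cloud), 0.012, tolerance = 0.05)
  # 15 degree tilt: the projected section is an ellipse; stay within 10%
  R <- cottontraits:::rotation_align(c(0, 0, 1),
                                     c(sin(15 * pi / 180), 0,
                                       cos(15 * pi / 180)))
  tilted <- plant_cloud(tube %*% t(R), labels = rep(0L, 2000))
  expect_equal(stem_diameter(tilted), 0.010, tolerance = 0.10)
})

test_that("branch detection finds each branch exactly once on clean plants", {
  pl <- small_plant()
  records <- detect_branches(pl$cloud)
  expect_length(records, 4L)
  # attachment heights match the generator within a couple of centimeters
  att <- sort(vapply(records, function(r) r$attachment[3], 0))
  expect_lt(max(abs(att - sort(pl$truth$attachment_heights))), 0.03)
  # no branches: empty list, not an error
  pl0 <- generate_plant(plant_spec(n_branches = 0L, n_bolls = 0L, seed = 15))
  expect_length(detect_branches(pl0$cloud), 0L)
})

test_that("branches closer than eps at their attachments merge (known limit)", {
  # stem plus two parallel branches 1.5 cm apart in z
  stem <- make_tube(c(0, 0, 0), c(0, 0, 1), 0.8, 0.006, 6000)
  b1 <- make_tube(c(0.012, 0, 0.40), c(1, 0, 0.4), 0.25, 0.004, 3000)
  b2 <- make_tube(c(0.012, 0, 0.415), c(1, 0, 0.4), 0.25, 0.004, 3000)
  pc <- plant_cloud(rbind(stem, b1, b2),
                    labels = c(rep(0L, 6000), rep(1L, 6000)))
  records <- detect_branches(pc, boll_cutoff = FALSE)
  expect_length(records, 1L)
})

test_that("inclination is the angle of the dominant axis above horizontal", {
  line_record <- function(dir) {
    pts <- outer(seq(0, 0.1, length.out = 100), dir / sqrt(sum(dir^2)))
    pts <- pts + matrix(rnorm(300, sd = 1e-5), 100, 3)
    structure(list(points = pts), class = "branch_record")
  }
  expect_equal(branch_inclination(line_record(c(1, 0, 1))), 45, tolerance = 0.1)
  expect_equal(branch_inclination(line_record(c(1, 0, 0))), 0, tolerance = 0.1)
  expect_equal(branch_inclination(line_record(c(0, 0, 1))), 90, tolerance = 0.1)
  expect_equal(branch_inclination(line_record(c(0, -2, 1))),
               atan2(1, 2) * 180 / pi, tolerance = 0.1)
})

test_that("a generated 35-degree branch is recovered within 2 degrees", {
  pl <- generate_plant(plant_spec(stem_height = 0.8, n_branches = 1L,
                                  branch_angles = 35, n_bolls = 1L,
                                  seed = 16))
  records <- detect_branches(pl$cloud)
  expect_length(records, 1L)
  expect_equal(branch_inclination(records[[1]]), 35, tolerance = 0.06)
  expect_equal(branch_diameter(records[[1]]),
               pl$truth$branch_diameters[1],
               tolerance = 0.15)
})

test_that("branch diameter of an already-vertical branch equals a direct fit", {
  tube <- make_tube(c(0, 0, 0), c(0, 0, 1), 0.1, 0.004, 1500)
  rec <- structure(list(points = tube), class = "branch_record")
  direct <- 2 * fit_circle_pratt(tube[tube[, 3] <= min(tube[, 3]) + 0.01,
                                      1:2])$radius
  expect_equal(branch_diameter(rec), direct, tolerance = 1e-6)
  # rotated member axis is parallel to z after alignment
  a <- cottontraits:::branch_axis(tube)
  R <- cottontraits:::rotation_align(a, c(0, 0, 1))
  expect_lt(acos(min(1, (R %*% a)[3])), 1e-6)
})

test_that("inclination is invariant to z-rotation and translation", {
  pl <- generate_plant(plant_spec(stem_height = 0.8, n_branches = 3L,
                                  n_bolls = 3L, seed = 17))
  base <- sort(vapply(detect_branches(pl$cloud), branch_inclination, 0))
  th <- 1.1
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  moved <- pl$cloud
  moved$coords <- sweep(pl$cloud$coords %*% t(Rz), 2, c(0.5, -1, 0.25), `+`)
  rotated <- sort(vapply(detect_branches(moved), branch_inclination, 0))
  expect_equal(rotated, base, tolerance = 1e-6)
})

test_that("node grouping follows the 1 cm rule on sorted cluster minima", {
  fake <- function(mz) structure(list(min_z = mz, points = diag(3),
                                      attachment = c(0, 0, mz)),
                                 class = "branch_record")
  stem <- plant_cloud(cbind(0, 0, seq(0, 1, length.out = 200)),
                      labels = rep(0L, 200))
  out <- detect_nodes(lapply(c(0.10, 0.105, 0.30), fake), stem)
  expect_equal(out$n_nodes, 2L)
  expect_equal(out$node_of, c(1L, 1L, 2L))
  out8 <- detect_nodes(lapply(seq(0.1, 0.8, 0.1), fake), stem)
  expect_equal(out8$n_nodes, 8L)
  expect_equal(detect_nodes(list(), stem)$n_nodes, 0L)
})

test_that("a generated two-branch node yields one fewer node than branches", {
  pl <- generate_plant(plant_spec(stem_height = 1.0, n_branches = 6L,
                                  n_bolls = 6L, same_node_pairs = 1L,
                                  seed = 18))
  tr <- extract_all(pl$cloud)
  expect_equal(tr$n_branches, 6L)
  expect_equal(tr$n_nodes, 5L)
})

test_that("well-separated bolls count one each; fused pairs count by size", {
  set.seed(19)
  centers <- cbind(runif(10, -0.3, 0.3), runif(10, -0.3, 0.3),
                   seq(0.3, 1.2, length.out = 10))
  pts <- do.call(rbind, lapply(seq_len(10),
                               function(i) make_sphere(centers[i, ], 0.02)))
  pc <- plant_cloud(pts, labels = rep(2L, nrow(pts)))
  res <- count_bolls(pc)
  expect_equal(res$n_bolls, 10L)
  expect_equal(nrow(res$clusters), 10L)

  # 8 singletons plus one fused pair whose cluster is ~2x the mean size
  set.seed(20)
  centers8 <- cbind(runif(8, -0.3, 0.3), runif(8, -0.3, 0.3),
                    seq(0.3, 1.0, length.out = 8))
  pts8 <- do.call(rbind, lapply(seq_len(8),
                                function(i) make_sphere(centers8[i, ], 0.02)))
  pair <- rbind(make_sphere(c(0.4, 0.4, 0.5), 0.02),
                make_sphere(c(0.42, 0.4, 0.5), 0.02))
  pc2 <- plant_cloud(rbind(pts8, pair), labels = rep(2L, nrow(pts8) + nrow(pair)))
  res2 <- count_bolls(pc2)
  expect_equal(res2$n_bolls, 10L)
  expect_equal(res2$outlier_counts, 2L)
})

test_that("clusters shorter than 3 cm (squares) are excluded", {
  # squashed ellipsoid: z-extent 2 cm
  s <- make_sphere(c(0, 0, 0.5), 0.02)
  s[, 3] <- 0.5 + (s[, 3] - 0.5) * 0.5
  pc <- plant_cloud(s, labels = rep(2L, nrow(s)))
  expect_equal(count_bolls(pc)$n_bolls, 0L)
  # no boll points at all
  pc2 <- plant_cloud(diag(3), labels = rep(0L, 3))
  expect_equal(count_bolls(pc2)$n_bolls, 0L)
})

test_that("boll counting is invariant to point order and rigid translation", {
  pl <- small_plant()
  base <- count_bolls(pl$cloud)$n_bolls
  set.seed(21)
  perm <- sample(n_points(pl$cloud))
  shuffled <- plant_cloud(pl$cloud$coords[perm, ], labels = pl$cloud$labels[perm])
  expect_equal(count_bolls(shuffled)$n_bolls, base)
  moved <- pl$cloud
  moved$coords <- sweep(moved$coords, 2, c(5, -3, 11), `+`)
  expect_equal(count_bolls(moved)$n_bolls, base)
})

test_that("DBSCAN agrees with the brute-force density-reachability oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(200:1000, 1)
    k <- sample(2:5, 1)
    centers <- matrix(runif(3 * k, 0, 1), k, 3)
    coords <- centers[sample(k, n, replace = TRUE), ] +
      matrix(rnorm(3 * n, sd = 0.03), n, 3)
    eps <- runif(1, 0.03, 0.08)
    min_pts <- sample(3:12, 1)
    mine <- cottontraits:::cpp_dbscan(coords, eps, min_pts)
    oracle <- brute_dbscan(coords, eps, min_pts)
    expect_true(same_partition(mine, oracle))
  }
})

test_that("extract_all is deterministic and degrades gracefully", {
  pl <- small_plant()
  a <- extract_all(pl$cloud)
  b <- extract_all(pl$cloud)
  expect_identical(traits_row(a), traits_row(b))
  # stem-only plant: zero branch/node/boll counts, stem traits still present
  pl0 <- generate_plant(plant_spec(stem_height = 0.6, n_branches = 0L,
                                   n_bolls = 0L, seed = 22))
  tr0 <- extract_all(pl0$cloud)
  expect_equal(tr0$n_branches, 0L)
  expect_equal(tr0$n_nodes, 0L)
  expect_equal(tr0$n_bolls, 0L)
  expect_equal(tr0$stem_height, 0.6, tolerance = 0.01)
})

test_that("label noise far from the stem does not change the branch count", {
  pl <- small_plant()
  cl <- pl$cloud
  stem_xyz <- cl$coords[cl$labels == 0L, ]
  d <- cottontraits:::nn_dist_to_set(cl$coords, stem_xyz, cap = 0.5)
  far <- which(d > 0.06 & cl$labels == 1L)
  set.seed(23)
  flip <- sample(far, min(length(far), round(0.01 * n_points(cl))))
  noisy <- cl
  noisy$labels[flip] <- 2L
  expect_equal(length(detect_branches(noisy)), length(detect_branches(cl)))
})

test_that("estimated stem height never exceeds the generator's span", {
  ex <- perturbed_experiment()
  expect_true(all(ex$est$stem_height <= ex$truth$stem_height + 1e-9))
})
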