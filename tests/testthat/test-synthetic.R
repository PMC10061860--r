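test_that("generated plants carry all three parts and echo their spec", {
  pl <- small_plant()
  expect_setequal(unique(pl$cloud$labels), c(0L, 1L, 2L))
  expect_equal(pl$truth$n_branches, 4L)
  expect_equal(pl$truth$n_nodes, 4L)
  expect_equal(pl$truth$n_bolls, 5L)
  expect_equal(pl$truth$stem_diameter, 0.014)
  expect_equal(pl$truth$stem_height, 0.7, tolerance = 0.01)
  expect_true(all(pl$truth$branch_angles >= 0 & pl$truth$branch_angles < 90))
})

test_that("same seed reproduces a byte-identical cloud", {
  sp <- plant_spec(n_branches = 3L, n_bolls = 4L, seed = 21)
  a <- generate_plant(sp)
  b <- generate_plant(sp)
  expect_identical(a$cloud$coords, b$cloud$coords)
  expect_identical(a$cloud$labels, b$cloud$labels)
  c <- generate_plant(plant_spec(n_branches = 3L, n_bolls = 4L, seed = 22))
  expect_false(identical(a$cloud$coords, c$cloud$coords))
})

test_that("branches attached within 1 cm share a node in the ground truth", {
  sp <- plant_spec(stem_height = 1.0, n_branches = 6L, n_bolls = 6L,
                   same_node_pairs = 1L, seed = 5)
  pl <- generate_plant(sp)
  expect_equal(pl$truth$n_nodes, pl$truth$n_branches - 1L)
  # explicit attachment heights, 5 mm apart
  sp2 <- plant_spec(n_branches = 2L, node_heights = c(0.300, 0.305),
                    n_bolls = 2L, seed = 6)
  expect_equal(generate_plant(sp2)$truth$n_nodes, 1L)
})

test_that("invalid specifications are rejected", {
  expect_error(plant_spec(boll_radius = 0.01), "0.015")
  expect_error(plant_spec(n_branches = 2L, node_heights = c(0.5, 1.5)),
               "strictly inside")
  expect_error(plant_spec(n_branches = 2L, branch_angles = c(95, 10)), "90")
  expect_error(plant_spec(stem_height = -1), "positive")
  expect_error(plant_spec(n_bolls = 2L, connected_boll_pairs = 2L), "pairs")
})

test_that("perturbation with zero fraction is the identity", {
  pl <- small_plant()
  out <- perturb_labels(pl$cloud, "boundary_swap", fraction = 0, seed = 1)
  expect_identical(out$labels, pl$cloud$labels)
})

test_that("region_flip relabels exactly the blob and nothing else", {
  pl <- small_plant()
  cl <- pl$cloud
  stem_idx <- which(cl$labels == 0L)
  center <- cl$coords[stem_idx[which.min(abs(cl$coords[stem_idx, 3] - 0.35))], ]
  out <- perturb_labels(cl, "region_flip", region_size = 0.02,
                        from = "main_stem", center = center, seed = 1)
  d2 <- rowSums(sweep(cl$coords, 2, center)^2)
  expected <- which(d2 <= 0.02^2 & cl$labels == 0L)
  changed <- which(out$labels != cl$labels)
  expect_identical(changed, expected)
  expect_true(all(out$labels[changed] == 1L))
  expect_identical(out$coords, cl$coords)
})

test_that("boundary swap flips roughly fraction of the boundary points", {
  pl <- small_plant()
  cl <- pl$cloud
  # oracle: brute-force boundary points (within 1 cm of another class)
  n <- n_points(cl)
  set.seed(42)
  sub <- cl
  boundary <- integer(0)
  for (cls in 0:2) {
    sel <- which(cl$labels == cls)
    oth <- cl$coords[cl$labels != cls & cl$labels >= 0, , drop = FALSE]
    d <- cottontraits:::nn_dist_to_set(cl$coords[sel, , drop = FALSE], oth)
    boundary <- c(boundary, sel[d <= 0.01])
  }
  out <- perturb_labels(cl, "boundary_swap", fraction = 0.1,
                        region_size = 0.01, seed = 99)
  flipped <- sum(out$labels != cl$labels)
  # binomial(length(boundary), 0.1), +/- 4 sd
  expect_gt(flipped, 0.1 * length(boundary) - 4 * sqrt(0.09 * length(boundary)))
  expect_lt(flipped, 0.1 * length(boundary) + 4 * sqrt(0.09 * length(boundary)))
  # flips occur only on boundary points
  expect_true(all(which(out$labels != cl$labels) %in% boundary))
})

test_that("outlier noise is appended and then removed by SOR", {
  pl <- small_plant()
  cl <- pl$cloud
  expect_identical(add_outlier_noise(cl, 0L, 1), cl)
  ext <- max(dist(apply(cl$coords, 2, range)))
  noisy <- add_outlier_noise(cl, 150L, radius = 5 * ext, seed = 3)
  expect_equal(n_points(noisy), n_points(cl) + 150L)
  expect_true(all(noisy$labels[seq_len(n_points(cl))] == cl$labels))
  res <- sor_denoise(noisy)
  injected <- n_points(cl) + seq_len(150L)
  expect_gte(mean(injected %in% res$removed), 0.9)
})
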