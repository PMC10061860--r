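# Fixture builders and session-cached experiments (generated in code; no data
# files). The cache avoids re-running the 20-plant cohorts for every block
# that inspects them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# 3 x 3 x 3 grid, 1 cm spacing
grid_cloud <- function(spacing = 0.01, extra = NULL) {
  g <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2)) * spacing
  plant_cloud(rbind(g, extra))
}

# surface-sampled tube, for hand-built geometry in tests
make_tube <- function(p0, dir, len, radius, n, s_min = 0) {
  dir <- dir / sqrt(sum(dir^2))
  s <- seq(s_min, len, length.out = n)
  phi <- (seq_len(n) * 2.399963) %% (2 * pi)   # deterministic spiral
  e1 <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- e1 - sum(e1 * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
          dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  matrix(p0, n, 3, byrow = TRUE) + outer(s, dir) +
    radius * (outer(cos(phi), e1) + outer(sin(phi), e2))
}

# surface-sampled sphere with enough density for the standard boll clustering
make_sphere <- function(center, r, pts_per_cm2 = 160) {
  n <- max(10L, round(4 * pi * r^2 * 1e4 * pts_per_cm2))
  g <- matrix(rnorm(3 * n), n, 3)
  g <- g / sqrt(rowSums(g^2))
  sweep(g * r, 2, center, `+`)
}

# small plant used by several unit tests (fast to extract)
small_plant <- function() {
  cached("small_plant",
         generate_plant(plant_spec(stem_height = 0.7, stem_diameter = 0.014,
                                   n_branches = 4L, n_bolls = 5L, seed = 11)))
}

clean_experiment <- function() {
  cached("clean_experiment",
         run_recovery_experiment(n_plants = 20L, seed = 1L, perturb = FALSE))
}

perturbed_experiment <- function() {
  cached("perturbed_experiment",
         run_recovery_experiment(n_plants = 20L, seed = 1L, perturb = TRUE))
}

boll_experiment <- function() {
  cached("boll_experiment",
         run_boll_count_experiment(n_plants = 20L, seed = 1L, n_connected = 5L))
}
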