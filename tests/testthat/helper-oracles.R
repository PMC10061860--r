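# Independent brute-force oracles used to cross-check the implementation.

# exhaustive SOR: O(N^2) distance matrix, mean distance to k nearest
brute_sor_removed <- function(coords, k = 6L, std_mult = 1.0) {
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  mean_knn <- apply(d, 1, function(row) mean(sort(row)[seq_len(k)]))
  unname(which(mean_knn > mean(mean_knn) + std_mult * sd(mean_knn)))
}

# exhaustive DBSCAN by density reachability (minPts includes the point itself)
brute_dbscan <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))  # includes self
  core <- vapply(nbrs, length, 0L) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      for (m in nbrs[[j]]) {
        if (labels[m] == 0L) {
          labels[m] <- cl
          if (core[m]) queue <- c(queue, m)
        }
      }
    }
  }
  labels
}

# do two clusterings define the same partition of non-noise points?
same_partition <- function(a, b) {
  if (!all((a == 0L) == (b == 0L))) return(FALSE)
  keep <- a != 0L
  a <- a[keep]; b <- b[keep]
  ta <- table(a, b)
  all(rowSums(ta > 0) == 1) && all(colSums(ta > 0) == 1)
}

# geometric least-squares circle fit (Gauss-Newton on sum (||p-c|| - r)^2)
geo_circle_fit <- function(points, init = NULL) {
  if (is.null(init)) {
    ctr <- colMeans(points)
    init <- c(ctr, mean(sqrt(rowSums(sweep(points, 2, ctr)^2))))
  }
  obj <- function(p) {
    ri <- sqrt((points[, 1] - p[1])^2 + (points[, 2] - p[2])^2)
    sum((ri - p[3])^2)
  }
  fit <- optim(init, obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  list(center = fit$par[1:2], radius = fit$par[3])
}

# uniformly sampled noisy circle
noisy_circle <- function(n, r, sigma, center = c(0, 0)) {
  th <- runif(n, 0, 2 * pi)
  cbind(center[1] + (r + rnorm(n, 0, sigma)) * cos(th),
        center[2] + (r + rnorm(n, 0, sigma)) * sin(th))
}
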