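# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# objective of the geometric-median problem
dist_sum <- function(p, pts) sum(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2))

# iteratively refined grid search for the geometric median (accuracy ~1e-5)
grid_median_oracle <- function(pts) {
  pts <- as.matrix(pts)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  center <- (lo + hi) / 2
  span <- max(hi - lo, 1)
  # gentle shrink: aggressive window halving loses flat near-singular minima
  for (stage in 1:14) {
    gx <- seq(center[1] - span / 2, center[1] + span / 2, length.out = 21)
    gy <- seq(center[2] - span / 2, center[2] + span / 2, length.out = 21)
    grid <- as.matrix(expand.grid(gx, gy))
    f <- apply(grid, 1, dist_sum, pts = pts)
    center <- grid[which.min(f), ]
    span <- span / 2
  }
  unname(center)
}

# exhaustive two-sided Mann-Whitney p-value by enumerating all assignments
# of the pooled sample to group a (valid for tie-free samples)
mw_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  ranks <- rank(pooled)
  offset <- n_a * (n_a + 1) / 2
  u_obs <- sum(ranks[seq_len(n_a)]) - offset
  combs <- utils::combn(length(pooled), n_a)
  u_all <- apply(combs, 2, function(idx) sum(ranks[idx]) - offset)
  m2 <- length(a) * length(b)          # 2 * mean of U
  # integer arithmetic on 2U keeps the tail comparison exact
  mean(abs(2 * u_all - m2) >= abs(2 * u_obs - m2))
}

# connected components of the strict distance-threshold graph (single linkage)
single_linkage_oracle <- function(x, y, threshold) {
  n <- length(x)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) < threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) { comp[ri] <- min(ri, rj); comp[rj] <- min(ri, rj) }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# brute-force occlusion of one patch: explicit loops, constant fill
occlude_brute <- function(volume, origin, patch, fill) {
  out <- volume
  for (dz in seq_len(patch[3]) - 1L)
    for (dy in seq_len(patch[2]) - 1L)
      for (dx in seq_len(patch[1]) - 1L)
        out[origin[1] + dx + 1L, origin[2] + dy + 1L, origin[3] + dz + 1L] <- fill
  out
}

# scorer wrapper that counts invocations
counting_scorer <- function(scorer) {
  env <- new.env()
  env$n <- 0L
  f <- function(volume) { env$n <- env$n + 1L; scorer(volume) }
  attr(f, "counter") <- env
  f
}

# small phantom + scorer fixture shared by occlusion tests
small_fixture <- function(shape = 16L, mask_lo = 6L, mask_hi = 9L, seed = 11L) {
  set.seed(seed)
  v <- array(stats::rnorm(shape^3, 0, 0.1), dim = rep(shape, 3L))
  mask <- array(FALSE, dim = rep(shape, 3L))
  mask[mask_lo:mask_hi, mask_lo:mask_hi, mask_lo:mask_hi] <- TRUE
  v[mask] <- v[mask] + 1
  list(volume = v, mask = mask, scorer = toy_scorer(mask))
}
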