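test_that("geometric median handles the degenerate and canonical cases", {
  expect_equal(geometric_median(matrix(c(3, 7), 1)), c(x = 3, y = 7))
  # two points: canonical midpoint of the optimal segment
  expect_equal(geometric_median(rbind(c(0, 0), c(10, 4))), c(x = 5, y = 2))
  # coincident points
  pts <- matrix(rep(c(2, 2), 8), ncol = 2, byrow = TRUE)
  expect_equal(geometric_median(pts), c(x = 2, y = 2))
})

test_that("geometric median agrees with a grid-search oracle to 1e-3", {
  # equilateral triangle: the Fermat point is the centroid
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  med <- geometric_median(tri)
  expect_equal(unname(med), colMeans(tri), tolerance = 1e-3)
  expect_lt(sqrt(sum((med - grid_median_oracle(tri))^2)), 1e-3)

  set.seed(17)
  for (rep in 1:6) {
    pts <- cbind(runif(sample(3:12, 1), 0, 100), runif(1, 0, 100) + rnorm(1))
    pts <- matrix(runif(2 * sample(3:12, 1), 0, 100), ncol = 2)
    med <- geometric_median(pts)
    oracle <- grid_median_oracle(pts)
    # compare objective values: distinct near-optimal points are acceptable
    expect_lt(dist_sum(med, pts) - dist_sum(oracle, pts), 1e-3)
    expect_lt(sqrt(sum((med - oracle)^2)), 1e-3)
    # median stays inside the bounding box of its points
    expect_true(all(med >= apply(pts, 2, min) - 1e-9) &&
                  all(med <= apply(pts, 2, max) + 1e-9))
  }
})

test_that("sequential clustering follows the strict 50 px threshold rule", {
  one <- data.frame(x = 10, y = 10)
  res <- cluster_annotations(one, threshold = 50)
  expect_identical(nrow(res$clusters), 1L)
  expect_identical(res$clusters$n_members, 1L)

  near <- data.frame(x = c(0, 40), y = c(0, 0))
  expect_identical(nrow(cluster_annotations(near, 50)$clusters), 1L)
  far <- data.frame(x = c(0, 60), y = c(0, 0))
  expect_identical(nrow(cluster_annotations(far, 50)$clusters), 2L)
  # exactly at the threshold: strict inequality founds a new cluster
  at <- data.frame(x = c(0, 50), y = c(0, 0))
  expect_identical(nrow(cluster_annotations(at, 50)$clusters), 2L)

  expect_identical(nrow(cluster_annotations(data.frame(x = numeric(0),
                                                       y = numeric(0)))$clusters),
                   0L)
})

test_that("clustering partitions the points (no loss, no duplication)", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    anchors <- data.frame(x = runif(n, 0, 500), y = runif(n, 0, 500),
                          reader_id = sample(sprintf("r%02d", 1:8), n, TRUE))
    res <- cluster_annotations(anchors, threshold = 50)
    expect_identical(sum(res$clusters$n_members), n)
    expect_identical(sort(unique(res$assignments$cluster_id)),
                     res$clusters$cluster_id)
    expect_identical(nrow(res$assignments), n)
    # cluster medians lie inside their members' bounding boxes
    for (k in res$clusters$cluster_id) {
      m <- res$assignments[res$assignments$cluster_id == k, ]
      expect_gte(res$clusters$median_x[k], min(m$x) - 1e-6)
      expect_lte(res$clusters$median_x[k], max(m$x) + 1e-6)
      expect_gte(res$clusters$median_y[k], min(m$y) - 1e-6)
      expect_lte(res$clusters$median_y[k], max(m$y) + 1e-6)
    }
  }
})

test_that("well-separated jittered ROIs are recovered with full purity", {
  set.seed(31)
  centers <- rbind(c(80, 80), c(300, 80), c(80, 300))
  truth <- rep(1:3, each = 12)
  anchors <- data.frame(
    x = centers[truth, 1] + rnorm(36, 0, 5),
    y = centers[truth, 2] + rnorm(36, 0, 5),
    reader_id = sprintf("r%02d", rep(1:12, 3)))
  res <- cluster_annotations(anchors, threshold = 50)
  expect_identical(nrow(res$clusters), 3L)
  # purity: each cluster contains exactly one true ROI
  expect_identical(unname(vapply(split(truth, res$assignments$cluster_id),
                                 function(g) length(unique(g)), 0L)),
                   rep(1L, 3))
  # agrees with the single-linkage oracle
  oracle <- single_linkage_oracle(anchors$x, anchors$y, 50)
  expect_identical(length(unique(oracle)), 3L)
})

test_that("threshold sweep reproduces the two-point arithmetic", {
  one <- data.frame(x = 10, y = 10)
  sw <- sweep_threshold(one)
  expect_identical(sw$n_clusters, rep(1L, 10))
  expect_identical(sw$threshold, seq(10, 100, by = 10))

  two <- data.frame(x = c(0, 55), y = c(0, 0))
  sw <- sweep_threshold(two)
  expect_identical(sw$n_clusters[sw$threshold <= 50], rep(2L, 5))
  expect_identical(sw$n_clusters[sw$threshold >= 60], rep(1L, 5))
})

test_that("cross-variant cluster merging unions nearby medians", {
  mk <- function(xy, variant) {
    df <- data.frame(annotation_id = paste0(variant, seq_len(nrow(xy))),
                     x = xy[, 1], y = xy[, 2], image_variant = variant)
    cluster_annotations(df, threshold = 50)
  }
  # disjoint medians: concatenation, no merge
  a <- mk(rbind(c(0, 0), c(2, 0)), "o")
  b <- mk(rbind(c(300, 300), c(302, 300)), "s")
  merged <- merge_registered_clusters(a, b, 50)
  expect_identical(nrow(merged$clusters), 2L)
  expect_identical(sum(merged$clusters$n_members), 4L)

  # identical medians: single merged cluster with union membership
  b2 <- mk(rbind(c(0, 0), c(2, 0)), "s")
  merged2 <- merge_registered_clusters(a, b2, 50)
  expect_identical(nrow(merged2$clusters), 1L)
  expect_identical(merged2$clusters$n_members, 4L)

  # transitive case: two saliency clusters each within 50 px of one
  # original cluster (but 80 px from each other) all collapse together
  mid <- mk(matrix(c(100, 100), 1), "o")
  sides <- mk(rbind(c(60, 100), c(140, 100)), "s")
  expect_identical(nrow(sides$clusters), 2L)
  merged3 <- merge_registered_clusters(mid, sides, 50)
  expect_identical(nrow(merged3$clusters), 1L)
  expect_identical(merged3$clusters$n_members, 3L)
  # matches the transitive-closure oracle on the cluster medians
  oracle <- single_linkage_oracle(c(100, 60, 140), c(100, 100, 100), 50)
  expect_identical(length(unique(oracle)), 1L)
})
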