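#' Geometric median of 2D points (Weiszfeld iteration)
#'
#' The geometric median minimizes the sum of Euclidean distances to the
#' points. One point returns that point; two points return their midpoint
#' (any point of the segment is optimal; the midpoint is the canonical
#' deterministic choice). For three or more points, Weiszfeld's fixed-point
#' iteration is run from the centroid with an epsilon guard against iterates
#' that coincide with a data point. Weiszfeld's linear rate collapses on
#' ill-conditioned configurations (minimizer close to a data point, or
#' near-collinear points with a flat valley); when the displacement
#' criterion is not met within `max_iter`, the iterate is polished with a
#' quasi-Newton step (BFGS on the smooth objective) and a warning is raised
#' only if that also fails to improve the objective.
#'
#' @param points numeric matrix or data frame with two columns (x, y).
#' @param tol convergence tolerance on the iterate displacement (pixels).
#' @param max_iter maximum number of Weiszfeld iterations before the
#'   quasi-Newton polish takes over.
#' @return numeric vector `c(x, y)`, always inside the points' bounding box.
#' @export
geometric_median <- function(points, tol = 1e-6, max_iter = 1000L) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (nrow(pts) == 0L) stop("at least one point is required", call. = FALSE)
  if (!all(is.finite(pts))) stop("points must be finite", call. = FALSE)
  if (nrow(pts) == 1L) return(c(x = pts[1L, 1L], y = pts[1L, 2L]))
  if (nrow(pts) == 2L) return(c(x = mean(pts[, 1L]), y = mean(pts[, 2L])))
  eps <- 1e-9
  dists <- function(y) {
    d <- sqrt((pts[, 1L] - y[1L])^2 + (pts[, 2L] - y[2L])^2)
    d[d < eps] <- eps
    d
  }
  y <- colMeans(pts)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- 1 / dists(y)
    y_new <- c(sum(pts[, 1L] * w), sum(pts[, 2L] * w)) / sum(w)
    done <- sqrt(sum((y_new - y)^2)) < tol
    y <- y_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged) {
    obj <- function(p) sum(dists(p))
    grad <- function(p) {
      d <- dists(p)
      c(sum((p[1L] - pts[, 1L]) / d), sum((p[2L] - pts[, 2L]) / d))
    }
    fit <- tryCatch(
      stats::optim(y, obj, grad, method = "BFGS",
                   control = list(reltol = 1e-14, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) && fit$value <= obj(y)) {
      # clamp to the bounding box (BFGS has no hull constraint)
      y <- pmin(pmax(fit$par, apply(pts, 2L, min)), apply(pts, 2L, max))
    } else {
      warning("geometric median did not converge; returning the last iterate",
              call. = FALSE)
    }
  }
  c(x = y[1L], y = y[2L])
}

#' Cluster annotation anchors by sequential geometric-median assignment
#'
#' Clusters the upper-left rectangle anchors of one case's annotations.
#' Points are processed in a deterministic order (sorted by `reader_id`, then
#' original row order); each point joins the existing cluster whose geometric
#' median is nearest if that distance is strictly below the threshold
#' (default 50 px), otherwise it founds a new cluster. The joined cluster's
#' median is recomputed after every addition. Every point ends up in exactly
#' one cluster.
#'
#' @param anchors data frame with columns `x`, `y` and optionally
#'   `annotation_id`, `reader_id`, `case_id`, `image_variant`.
#' @param threshold clustering distance threshold in display pixels.
#' @param order `"sorted"` (by reader then row; default), `"given"` (row
#'   order), or `"random"` (seeded shuffle, for order-sensitivity checks).
#' @param seed RNG seed used only when `order = "random"`.
#' @return an object of class `roi_clusters`: list with `assignments` (one
#'   row per point: `annotation_id`, `x`, `y`, `cluster_id`, carried-over
#'   id columns) and `clusters` (one row per cluster: `cluster_id`,
#'   `n_members`, `median_x`, `median_y`).
#' @export
cluster_annotations <- function(anchors, threshold = 50,
                                order = c("sorted", "given", "random"),
                                seed = NULL) {
  order <- match.arg(order)
  stopifnot(is.data.frame(anchors), all(c("x", "y") %in% names(anchors)),
            is.numeric(threshold), threshold > 0)
  n <- nrow(anchors)
  if (!is.null(anchors$case_id) && length(unique(anchors$case_id)) > 1L)
    stop("anchors must all come from a single case", call. = FALSE)
  if (n == 0L)
    return(structure(list(assignments = cbind(anchors, cluster_id = integer(0)),
                          clusters = data.frame(cluster_id = integer(0),
                                                n_members = integer(0),
                                                median_x = numeric(0),
                                                median_y = numeric(0)),
                          threshold = threshold),
                     class = "roi_clusters"))
  if (!all(is.finite(anchors$x)) || !all(is.finite(anchors$y)) ||
      any(anchors$x < 0) || any(anchors$y < 0))
    stop("anchor coordinates must be finite and non-negative", call. = FALSE)

  ord <- switch(order,
                sorted = if (is.null(anchors$reader_id)) seq_len(n) else
                  base::order(anchors$reader_id, seq_len(n)),
                given = seq_len(n),
                random = {
                  if (!is.null(seed)) set.seed(seed)
                  sample.int(n)
                })
  xy <- cbind(anchors$x, anchors$y)
  members <- list()            # integer row indices per cluster
  medians <- matrix(numeric(0), ncol = 2L)
  assign_id <- integer(n)
  for (i in ord) {
    p <- xy[i, ]
    if (length(members) > 0L) {
      d <- sqrt((medians[, 1L] - p[1L])^2 + (medians[, 2L] - p[2L])^2)
      j <- which.min(d)
    } else j <- NA_integer_
    if (!is.na(j) && d[j] < threshold) {
      members[[j]] <- c(members[[j]], i)
      medians[j, ] <- geometric_median(xy[members[[j]], , drop = FALSE])
    } else {
      members[[length(members) + 1L]] <- i
      medians <- rbind(medians, p)
      j <- length(members)
    }
    assign_id[i] <- j
  }
  assignments <- anchors
  assignments$cluster_id <- assign_id
  clusters <- data.frame(
    cluster_id = seq_along(members),
    n_members = vapply(members, length, 0L),
    median_x = medians[, 1L],
    median_y = medians[, 2L])
  structure(list(assignments = assignments, clusters = clusters,
                 threshold = threshold),
            class = "roi_clusters")
}

#' @export
print.roi_clusters <- function(x, ...) {
  cat(sprintf("%d cluster(s) over %d annotation anchor(s), threshold %g px\n",
              nrow(x$clusters), nrow(x$assignments), x$threshold))
  invisible(x)
}

#' Cluster counts across a range of distance thresholds
#'
#' Re-runs [cluster_annotations()] at each threshold (default 10 to 100 px in
#' steps of 10) and reports the cluster count, reproducing the sweep used to
#' locate the cluster-count plateau that motivates the 50 px default.
#'
#' @inheritParams cluster_annotations
#' @param thresholds numeric vector of thresholds in pixels.
#' @return data frame with columns `threshold` and `n_clusters`.
#' @export
sweep_threshold <- function(anchors, thresholds = seq(10, 100, by = 10), ...) {
  counts <- vapply(thresholds, function(t)
    nrow(cluster_annotations(anchors, threshold = t, ...)$clusters), 0L)
  data.frame(threshold = thresholds, n_clusters = counts)
}

#' Merge clusters from the original and saliency image variants
#'
#' Readers could annotate either the original image or the saliency overlay;
#' both share one pixel frame (identity registration), so clusters from the
#' two variants that sit on the same image area are combined. Clusters whose
#' medians lie within `merge_threshold` of each other are unioned, merging
#' pair after pair until no qualifying pair remains (i.e. the transitive
#' closure of the proximity relation on the input medians); each merged
#' cluster's median is then recomputed from its pooled anchors.
#'
#' @param clusters_original,clusters_saliency `roi_clusters` objects from
#'   the same case.
#' @param merge_threshold merge distance in pixels (default: the clustering
#'   threshold, 50 px).
#' @return a combined `roi_clusters` object with renumbered cluster ids.
#' @export
merge_registered_clusters <- function(clusters_original, clusters_saliency,
                                      merge_threshold = 50) {
  stopifnot(inherits(clusters_original, "roi_clusters"),
            inherits(clusters_saliency, "roi_clusters"),
            merge_threshold > 0)
  a <- clusters_original$assignments
  b <- clusters_saliency$assignments
  if (nrow(b) > 0L) b$cluster_id <- b$cluster_id + max(0L, a$cluster_id)
  pool <- rbind(a, b)
  if (nrow(pool) == 0L)
    return(structure(list(assignments = pool,
                          clusters = clusters_original$clusters,
                          threshold = merge_threshold),
                     class = "roi_clusters"))

  groups <- split(seq_len(nrow(pool)), pool$cluster_id)
  groups <- groups[order(as.integer(names(groups)))]
  meds <- t(vapply(groups, function(rows)
    geometric_median(pool[rows, c("x", "y")]), numeric(2L)))
  # union-find closure of the proximity relation on the input medians
  k <- nrow(meds)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1L) {
    dm <- as.matrix(stats::dist(meds))
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      if (dm[i, j] < merge_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(k), find, 0L)
  comp <- match(roots, unique(roots))   # renumber by first appearance
  merged <- lapply(seq_len(max(comp)), function(g)
    unlist(groups[comp == g], use.names = FALSE))
  meds <- t(vapply(merged, function(rows)
    geometric_median(pool[rows, c("x", "y")]), numeric(2L)))
  pool$cluster_id <- NA_integer_
  for (g in seq_along(merged)) pool$cluster_id[merged[[g]]] <- g
  clusters <- data.frame(
    cluster_id = seq_along(merged),
    n_members = vapply(merged, length, 0L),
    median_x = meds[, 1L],
    median_y = meds[, 2L])
  structure(list(assignments = pool, clusters = clusters,
                 threshold = merge_threshold),
            class = "roi_clusters")
}

#' Single-linkage comparison clustering
#'
#' Connected components of the graph joining anchor pairs at distance below
#' the threshold (single linkage). This is the comparison rule against which
#' the sequential geometric-median clustering is benchmarked; it is not used
#' by the pipeline itself.
#'
#' @inheritParams cluster_annotations
#' @return integer vector of cluster labels, one per row of `anchors`.
#' @export
cluster_single_linkage <- function(anchors, threshold = 50) {
  n <- nrow(anchors)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::dist(cbind(anchors$x, anchors$y)),
                      method = "single")
  # cutree merges at height <= h; shrink by epsilon for the strict rule
  stats::cutree(hc, h = threshold * (1 - 1e-12))
}
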