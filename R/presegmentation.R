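# Pre-segmentation: DBSCAN clustering, RANSAC linearity classification and
# the one-third-of-average noise rule.

#' Density-based clustering of a point cloud (DBSCAN)
#'
#' Standard DBSCAN over the 3D coordinates: points with at least `min_pts`
#' neighbours within `eps` are core points, clusters are the
#' density-reachability components of the core points, non-core points in no
#' cluster are noise. Backed by a grid-indexed C++ kernel.
#'
#' Defaults (eps 0.6 m, min_pts 10) are on the order of typical MLS point
#' spacing on street-tree crowns.
#'
#' @param cloud point-cloud tibble.
#' @param eps neighbourhood radius in meters (> 0).
#' @param min_pts core-point threshold (>= 1).
#' @return the cloud with an integer `cluster` column: ids 1..k in order of
#'   first appearance, `NA` for noise points.
#' @export
dbscan_cluster <- function(cloud, eps = 0.6, min_pts = 10) {
  stopifnot(eps > 0, min_pts >= 1)
  cloud <- as_point_cloud_keep(cloud)
  lab <- .dbscan_impl(cloud$x, cloud$y, cloud$z, eps, as.integer(min_pts))
  cloud$cluster <- ifelse(lab == 0L, NA_integer_, lab)
  cloud
}

# as_point_cloud but preserving extra columns (label, cluster, ...)
as_point_cloud_keep <- function(cloud) {
  core <- as_point_cloud(cloud)
  extra <- setdiff(names(cloud), names(core))
  for (nm in extra) core[[nm]] <- cloud[[nm]]
  core
}

#' Per-cluster point counts
#' @param cloud clustered point cloud (has a `cluster` column).
#' @return tibble with columns `cluster`, `n` (noise rows excluded).
#' @export
cluster_sizes <- function(cloud) {
  cloud |>
    dplyr::filter(!is.na(.data$cluster)) |>
    dplyr::count(.data$cluster, name = "n")
}

#' Robust 3D line fit by RANSAC
#'
#' Samples (or, for small clusters, exhaustively enumerates) point pairs,
#' scores the line through each pair by the number of cluster points within
#' `dist_threshold` of it, and returns the best line. The 0.4 m threshold
#' separates pole-like objects and bare trunk fragments (nearly all points
#' within 0.4 m of a line) from crowns.
#'
#' @param points matrix or tibble of candidate points (columns x, y, z).
#' @param dist_threshold inlier distance to the line, meters.
#' @param n_iter number of sampled pairs when the cluster is large.
#' @param seed integer seed; results are reproducible bit-for-bit.
#' @param exhaustive_max below this point count all pairs are tried, making
#'   the fit deterministic regardless of seed.
#' @return object of class `line_ransac`: fields `point`, `direction` (unit
#'   vector), `inlier_ratio`, `n_inliers`, `n`.
#' @export
fit_line_ransac <- function(points, dist_threshold = 0.4, n_iter = 200,
                            seed = 1L, exhaustive_max = 50L) {
  pts <- as.matrix(as_point_cloud(points)[, c("x", "y", "z")])
  n <- nrow(pts)
  if (n < 2) abort("fit_line_ransac needs at least 2 points")

  score_pair <- function(i, j) {
    d <- pts[j, ] - pts[i, ]
    len <- sqrt(sum(d^2))
    if (len < 1e-12) return(NULL)
    u <- d / len
    m <- sweep(pts, 2, pts[i, ])
    proj <- as.vector(m %*% u)
    d2 <- pmax(rowSums(m^2) - proj^2, 0)
    list(inliers = sum(d2 <= dist_threshold^2), point = pts[i, ], dir = u)
  }

  pairs <- if (n <= exhaustive_max) {
    utils::combn(n, 2)
  } else {
    with_local_seed(seed, function() {
      rbind(sample.int(n, n_iter, replace = TRUE),
            sample.int(n, n_iter, replace = TRUE))
    })
  }
  best <- NULL
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (i == j) next
    cand <- score_pair(i, j)
    if (!is.null(cand) && (is.null(best) || cand$inliers > best$inliers)) best <- cand
  }
  if (is.null(best)) {
    # all points coincident: any direction, everything an inlier
    best <- list(inliers = n, point = pts[1, ], dir = c(0, 0, 1))
  }
  structure(
    list(point = unname(best$point), direction = unname(best$dir),
         inlier_ratio = best$inliers / n, n_inliers = best$inliers, n = n),
    class = "line_ransac"
  )
}

#' @export
print.line_ransac <- function(x, ...) {
  cat(sprintf("RANSAC line: %d/%d inliers (ratio %.3f), direction (%.3f, %.3f, %.3f)\n",
              x$n_inliers, x$n, x$inlier_ratio,
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Classify a cluster as linear or nonlinear
#'
#' A cluster is linear when the RANSAC line fit captures at least
#' `linear_ratio_cutoff` of its points within `dist_threshold`. Pole-like
#' distractors and bare trunk fragments come out linear; crowns do not.
#'
#' @param points cluster points (x, y, z).
#' @param linear_ratio_cutoff inlier-ratio cutoff, default 0.9.
#' @inheritParams fit_line_ransac
#' @return `"linear"` or `"nonlinear"`.
#' @export
classify_linearity <- function(points, linear_ratio_cutoff = 0.9,
                               dist_threshold = 0.4, n_iter = 200, seed = 1L) {
  pts <- as_point_cloud(points)
  if (nrow(pts) == 0) abort("classify_linearity needs a nonempty cluster")
  if (nrow(pts) == 1) return("linear")
  fit <- fit_line_ransac(pts, dist_threshold = dist_threshold,
                         n_iter = n_iter, seed = seed)
  if (fit$inlier_ratio >= linear_ratio_cutoff) "linear" else "nonlinear"
}

#' Classify every cluster of a clustered cloud
#'
#' @param cloud clustered point cloud (`cluster` column from
#'   [dbscan_cluster()]).
#' @inheritParams classify_linearity
#' @return tibble with columns `cluster`, `n`, `inlier_ratio`, `kind`.
#' @export
classify_clusters <- function(cloud, linear_ratio_cutoff = 0.9,
                              dist_threshold = 0.4, n_iter = 200, seed = 1L) {
  cloud |>
    dplyr::filter(!is.na(.data$cluster)) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_map(function(g, key) {
      fit <- fit_line_ransac(g, dist_threshold = dist_threshold,
                             n_iter = n_iter, seed = seed)
      tibble::tibble(
        cluster = key$cluster, n = nrow(g), inlier_ratio = fit$inlier_ratio,
        kind = if (fit$inlier_ratio >= linear_ratio_cutoff) "linear" else "nonlinear"
      )
    }) |>
    dplyr::bind_rows()
}

#' Drop small clusters by the one-third-of-average noise rule
#'
#' The mean point count m is taken over the NONLINEAR clusters only (the
#' linearity check exists so trunk fragments are not mistaken for noise);
#' clusters with fewer than m/3 points are flagged as noise. Linear clusters
#' are exempt by default so over-segmented trunk pieces survive to the merge
#' stage; set `exempt_linear = FALSE` to apply the m/3 cut to every cluster.
#' Counts exactly equal to m/3 are retained (the rule drops strictly-below).
#'
#' @param classes cluster classification tibble from [classify_clusters()]
#'   (columns `cluster`, `n`, `kind`).
#' @param exempt_linear keep linear clusters regardless of size.
#' @return `classes` with a logical `retained` column; the m/3 threshold is
#'   attached as attribute `"noise_threshold"`. If there are no nonlinear
#'   clusters everything is retained, with a warning.
#' @export
filter_noise_clusters <- function(classes, exempt_linear = TRUE) {
  stopifnot(all(c("cluster", "n", "kind") %in% names(classes)))
  nl <- classes$n[classes$kind == "nonlinear"]
  if (length(nl) == 0) {
    warn("no nonlinear clusters: noise rule skipped, all clusters retained")
    classes$retained <- TRUE
    attr(classes, "noise_threshold") <- 0
    return(classes)
  }
  thr <- mean(nl) / 3
  classes$retained <- classes$n >= thr
  if (exempt_linear) classes$retained <- classes$retained | classes$kind == "linear"
  attr(classes, "noise_threshold") <- thr
  classes
}

#' Apply a retention table to a clustered cloud
#'
#' Points of non-retained clusters get `cluster = NA`.
#'
#' @param cloud clustered point cloud.
#' @param classes output of [filter_noise_clusters()].
#' @return the cloud with dropped clusters turned to noise.
#' @export
apply_retention <- function(cloud, classes) {
  drop_ids <- classes$cluster[!classes$retained]
  cloud$cluster[cloud$cluster %in% drop_ids] <- NA_integer_
  cloud
}
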