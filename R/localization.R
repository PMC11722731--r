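# Tree localization by breast-height circle fitting and density-valley
# splitting of under-segmented clusters.

#' Breast-height slab of a cluster
#'
#' Returns the XY coordinates of points whose height above the cluster root
#' (its minimum z — the ground is assumed stripped, so the lowest stem point
#' approximates the root collar) falls in \[`lo`, `hi`\], by default the
#' 1.25–1.35 m band around breast height (1.3 m).
#'
#' @param points cluster points (x, y, z).
#' @param lo,hi slab bounds above the root, meters.
#' @return tibble of `x`, `y` (and `z`) of slab points; may have zero rows
#'   (attribute `"empty"` is then TRUE).
#' @export
slice_breast_height <- function(points, lo = 1.25, hi = 1.35) {
  pts <- as_point_cloud_keep(points)
  if (nrow(pts) == 0) {
    attr(pts, "empty") <- TRUE
    return(pts)
  }
  z_root <- min(pts$z)
  out <- pts[pts$z - z_root >= lo & pts$z - z_root <= hi, , drop = FALSE]
  attr(out, "empty") <- nrow(out) == 0
  out
}

#' Least-squares circle fit (Kåsa method)
#'
#' Fits a circle to 2D points by minimizing the algebraic residual
#' sum((x^2 + y^2 + A x + B y + C)^2) — linear in (A, B, C), solved by the
#' normal equations; then a = -A/2, b = -B/2, r = sqrt(a^2 + b^2 - C). The
#' fit is exact (to machine precision) for points lying on a circle.
#'
#' @param points2d matrix or data frame with columns x, y (>= 3 points, not
#'   collinear).
#' @return object of class `circle_fit`: `a`, `b` (center, m), `r` (radius,
#'   m), `rms_residual` (RMS of radial residuals, m), `n_points`.
#' @export
fit_circle_lsq <- function(points2d) {
  xy <- xy_of(points2d)
  if (nrow(xy) < 3) abort("circle fit needs at least 3 points")
  # solve in a centered frame: the normal equations are ill-conditioned for
  # small rings far from the origin (x, y nearly proportional to the
  # intercept column); translation equivariance makes centering exact
  mx <- mean(xy[, 1]); my <- mean(xy[, 2])
  x <- xy[, 1] - mx; y <- xy[, 2] - my
  ev <- eigen(crossprod(cbind(x, y)), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-12 * max(ev[1], 1e-300)) {
    abort("circle fit failed: points are collinear (singular system)")
  }
  M <- cbind(x, y, 1)
  rhs <- -(x^2 + y^2)
  theta <- solve(crossprod(M), crossprod(M, rhs))
  A <- theta[1]; B <- theta[2]; C <- theta[3]
  a <- -A / 2; b <- -B / 2
  r2 <- a^2 + b^2 - C
  if (r2 <= 0) abort("circle fit failed: non-positive squared radius")
  r <- sqrt(r2)
  res <- sqrt((x - a)^2 + (y - b)^2) - r
  a <- a + mx
  b <- b + my
  structure(
    list(a = a, b = b, r = r, rms_residual = sqrt(mean(res^2)),
         n_points = nrow(xy)),
    class = "circle_fit"
  )
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("circle fit: center (%.4f, %.4f), r = %.4f m, RMS %.2e m (n = %d)\n",
              x$a, x$b, x$r, x$rms_residual, x$n_points))
  invisible(x)
}

#' Locate trunks in every cluster by breast-height circle fits
#'
#' Per cluster: the breast-height slab is sub-clustered in XY by
#' single-linkage connected components at `linkage` meters, and each
#' component with at least `min_slab_pts` points is circle-fitted. Fits are
#' discarded when the radius is implausible (outside \[`r_min`, `r_max`\]),
#' the fit fails, or the component is not ring-like: points must cover at
#' least `arc_min` degrees of arc around the fitted center and the radial
#' RMS residual must stay below `rms_rel` times the radius. A stem slab is
#' a thin annulus; sign boards and foliage patches either subtend a narrow
#' arc or scatter radially however well a circle passes through them. Each
#' accepted fit center is one located tree.
#'
#' @param cloud clustered point cloud.
#' @param lo,hi breast-height slab bounds, meters above the cluster root.
#' @param linkage XY single-linkage gap closing components, meters.
#' @param r_min,r_max trunk-radius plausibility gate, meters.
#' @param min_slab_pts minimum component size worth fitting.
#' @param arc_min minimum angular coverage about the fitted center, degrees
#'   (checked in 30-degree sectors; 180 tolerates one-sided scan coverage).
#' @param rms_rel maximum radial RMS residual as a fraction of the fitted
#'   radius (0.25 accommodates bark roughness and sensor noise).
#' @return tibble with one row per accepted fit: `cluster`, `x`, `y`, `r`,
#'   `rms`, `n_slab`. Clusters without rows are unlocatable (empty or
#'   implausible slab).
#' @export
locate_trees <- function(cloud, lo = 1.25, hi = 1.35, linkage = 0.35,
                         r_min = 0.03, r_max = 1.5, min_slab_pts = 10,
                         arc_min = 180, rms_rel = 0.25) {
  ids <- sort(unique(cloud$cluster[!is.na(cloud$cluster)]))
  out <- lapply(ids, function(id) {
    pts <- cloud[!is.na(cloud$cluster) & cloud$cluster == id, ]
    slab <- slice_breast_height(pts, lo, hi)
    if (nrow(slab) < min_slab_pts) return(NULL)
    comp <- xy_components(slab$x, slab$y, linkage)
    fits <- lapply(split(seq_len(nrow(slab)), comp), function(idx) {
      if (length(idx) < min_slab_pts) return(NULL)
      fit <- tryCatch(fit_circle_lsq(slab[idx, ]), error = function(e) NULL)
      if (is.null(fit) || fit$r < r_min || fit$r > r_max) return(NULL)
      if (fit$rms_residual > rms_rel * fit$r) return(NULL)
      ang <- atan2(slab$y[idx] - fit$b, slab$x[idx] - fit$a)
      coverage <- 30 * sum(tabulate(floor((ang + pi) / (pi / 6)) + 1L, 12) > 0)
      if (coverage < arc_min) return(NULL)
      tibble::tibble(cluster = id, x = fit$a, y = fit$b, r = fit$r,
                     rms = fit$rms_residual, n_slab = length(idx))
    })
    dplyr::bind_rows(fits)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(cluster = integer(), x = double(), y = double(),
                          r = double(), rms = double(), n_slab = integer())
  }
  res
}

# single-linkage XY connected components at gap h
xy_components <- function(x, y, h) {
  n <- length(x)
  if (n == 1) return(1L)
  cl <- stats::hclust(stats::dist(cbind(x, y)), method = "single")
  stats::cutree(cl, h = h)
}

#' Is a cluster under-segmented?
#'
#' True when two or more accepted breast-height circle fits fall in one
#' cluster — multiple trunks, hence multiple trees glued together.
#'
#' @param fits per-cluster rows of the [locate_trees()] table.
#' @return logical.
#' @export
detect_undersegmentation <- function(fits) {
  nrow(fits) >= 2
}

#' Rotate a cluster so the trunk connection line is the +u axis
#'
#' For two or more trunk centers, the centers are ordered along their first
#' principal direction and the XY frame is rotated about Z so the line
#' through them runs along +u, with the first center at the origin. A pure
#' rotation: all pairwise distances are preserved.
#'
#' @param points cluster points (x, y, ...).
#' @param centers matrix or data frame of trunk centers (columns x, y).
#' @return list: `uv` (n x 2 matrix of rotated coordinates), `centers_u`
#'   (sorted trunk positions along the axis), `rotation` (2 x 2 matrix),
#'   `origin` (XY of the first trunk).
#' @export
align_to_trunk_axis <- function(points, centers) {
  ctr <- xy_of(centers)
  if (nrow(ctr) < 2) abort("align_to_trunk_axis needs at least 2 trunk centers")
  if (nrow(ctr) == 2) {
    d <- ctr[2, ] - ctr[1, ]
  } else {
    pc <- stats::prcomp(ctr)$rotation[, 1]
    d <- pc
  }
  len <- sqrt(sum(d^2))
  if (len < 1e-9) abort("coincident trunk centers: axis direction undefined")
  u_hat <- d / len
  # order centers along the axis; origin at the first
  proj <- as.vector((ctr - matrix(ctr[1, ], nrow(ctr), 2, byrow = TRUE)) %*% u_hat)
  ord <- order(proj)
  origin <- ctr[ord[1], ]
  R <- rbind(u_hat, c(-u_hat[2], u_hat[1]))  # rows: u, v
  pts <- xy_of(points)
  uv <- t(R %*% (t(pts) - origin))
  colnames(uv) <- c("u", "v")
  centers_u <- sort(as.vector((ctr - matrix(origin, nrow(ctr), 2, byrow = TRUE)) %*% u_hat))
  list(uv = uv, centers_u = centers_u, rotation = R, origin = origin)
}

#' Find the split boundary between trunks by the voxel density valley
#'
#' Along the rotated trunk-connection axis, the span between each adjacent
#' pair of trunk positions is divided into voxels of (approximately)
#' `voxel_width` and the point count per voxel is tallied; the boundary is
#' the center of the minimum-count voxel (ties broken toward the midpoint).
#' If fewer than two voxels fit between a pair, the boundary falls at the
#' midpoint, with a warning.
#'
#' @param u point coordinates along the trunk-connection axis (from
#'   [align_to_trunk_axis()]).
#' @param centers_u sorted trunk positions along the same axis.
#' @param voxel_width voxel size along the axis, meters.
#' @return object of class `split_plan`: `boundaries` (one per adjacent
#'   trunk pair), `profile` (tibble of voxel bins and counts), `centers_u`,
#'   `voxel_width`.
#' @export
find_boundary_voxel <- function(u, centers_u, voxel_width = 0.5) {
  stopifnot(voxel_width > 0, length(centers_u) >= 2)
  centers_u <- sort(centers_u)
  boundaries <- numeric(0)
  profile <- list()
  for (p in seq_len(length(centers_u) - 1)) {
    u1 <- centers_u[p]; u2 <- centers_u[p + 1]
    nbin <- floor((u2 - u1) / voxel_width)
    if (nbin < 2) {
      warn(sprintf("trunk pair %d: span %.2f m holds < 2 voxels; boundary at midpoint",
                   p, u2 - u1))
      boundaries <- c(boundaries, (u1 + u2) / 2)
      next
    }
    breaks <- seq(u1, u2, length.out = nbin + 1)
    counts <- tabulate(findInterval(u[u >= u1 & u <= u2], breaks,
                                    rightmost.closed = TRUE), nbin)
    centers <- (breaks[-1] + breaks[-(nbin + 1)]) / 2
    lo <- which(counts == min(counts))
    mid <- (u1 + u2) / 2
    pick <- lo[which.min(abs(centers[lo] - mid))]
    boundaries <- c(boundaries, centers[pick])
    profile[[p]] <- tibble::tibble(
      pair = p, bin_lo = breaks[-(nbin + 1)], bin_hi = breaks[-1],
      center = centers, n = counts,
      is_boundary = seq_len(nbin) == pick
    )
  }
  structure(
    list(boundaries = boundaries,
         profile = dplyr::bind_rows(profile),
         centers_u = centers_u, voxel_width = voxel_width),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split plan: %d boundar%s at u = %s (voxel %.2f m)\n",
              length(x$boundaries), if (length(x$boundaries) == 1) "y" else "ies",
              paste(sprintf("%.2f", x$boundaries), collapse = ", "),
              x$voxel_width))
  invisible(x)
}

#' Split an under-segmented cluster at its density-valley boundaries
#'
#' Partitions the cluster by each point's position along the trunk
#' connection axis against the plan's boundaries: k trunks give k children.
#' Children are disjoint and conserve the parent's points.
#'
#' @param points cluster points.
#' @param plan `split_plan` from [find_boundary_voxel()].
#' @param alignment the [align_to_trunk_axis()] result used for the plan
#'   (supplies the rotation; its `uv` must match `points` row for row).
#' @return the points tibble with an integer `part` column in 1..k.
#' @export
split_cluster <- function(points, plan, alignment) {
  pts <- as_point_cloud_keep(points)
  u <- alignment$uv[, 1]
  if (length(u) != nrow(pts)) abort("alignment does not match points")
  pts$part <- findInterval(u, sort(plan$boundaries)) + 1L
  pts
}
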