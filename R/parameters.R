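# Per-tree morphometry: height, DBH, crown hull, crown diameter, crown area.

#' Tree height
#'
#' Height of a segmented tree: the difference between the highest and
#' lowest point of its point set (ground assumed stripped).
#'
#' @param points tree points (needs z).
#' @return height in meters (>= 0).
#' @export
tree_height <- function(points) {
  pts <- as_point_cloud(points)
  if (nrow(pts) == 0) abort("tree_height: empty point set")
  max(pts$z) - min(pts$z)
}

#' Stand average height
#'
#' Arithmetic mean of the per-tree heights over the study area.
#'
#' @param heights numeric vector of tree heights, meters (length >= 1).
#' @return mean height, meters.
#' @export
stand_average_height <- function(heights) {
  if (length(heights) == 0) abort("stand_average_height: no heights")
  mean(heights)
}

#' Diameter at breast height
#'
#' DBH is twice the radius of the least-squares circle fitted to the
#' breast-height slab (points 1.25–1.35 m above the tree's lowest point).
#' The measurement is flagged unavailable when the slab is empty, the fit
#' fails, or the slab is not ring-like (radial RMS residual above `rms_rel`
#' of the radius) — a crown-only fragment slices into a filled disc that a
#' circle will happily pass through but that measures nothing.
#'
#' @param points tree points.
#' @param lo,hi breast-height slab bounds, meters above the root.
#' @param rms_rel ring-validity bound on rms_residual / r.
#' @return list: `dbh` (meters, NA when unavailable), `fit` (`circle_fit`
#'   or NULL), `available` (logical).
#' @export
dbh <- function(points, lo = 1.25, hi = 1.35, rms_rel = 0.25) {
  slab <- slice_breast_height(points, lo, hi)
  if (nrow(slab) < 3) {
    return(list(dbh = NA_real_, fit = NULL, available = FALSE))
  }
  fit <- tryCatch(fit_circle_lsq(slab), error = function(e) NULL)
  if (is.null(fit) || fit$rms_residual > rms_rel * fit$r) {
    return(list(dbh = NA_real_, fit = fit, available = FALSE))
  }
  list(dbh = 2 * fit$r, fit = fit, available = TRUE)
}

#' Crown convex hull
#'
#' Projects the whole tree onto the XY plane and builds the minimum convex
#' polygon with the quickhull recursion (see [quickhull()]); trunk points
#' are interior so the hull is, in practice, the crown outline. Also finds
#' the hull-vertex pair at maximum spacing (the crown diameter pair).
#'
#' @param points tree points (x, y at least 3 non-collinear).
#' @return object of class `convex_hull_2d`: `vertices` (CCW matrix),
#'   `diameter_pair` (2 x 2 matrix), `diameter` (m), `area` (m^2).
#' @export
crown_hull <- function(points) {
  xy <- xy_of(points)
  hull <- quickhull(xy)  # errors on degenerate input, naming the degeneracy
  nv <- nrow(hull)
  dmax <- -1; pair <- NULL
  for (i in seq_len(nv - 1)) {
    dx <- hull[(i + 1):nv, 1] - hull[i, 1]
    dy <- hull[(i + 1):nv, 2] - hull[i, 2]
    d2 <- dx^2 + dy^2
    j <- which.max(d2)
    if (d2[j] > dmax) {
      dmax <- d2[j]
      pair <- hull[c(i, i + j), , drop = FALSE]
    }
  }
  structure(
    list(vertices = hull, diameter_pair = pair, diameter = sqrt(dmax),
         area = shoelace_area(hull)),
    class = "convex_hull_2d"
  )
}

#' @export
print.convex_hull_2d <- function(x, ...) {
  cat(sprintf("convex hull: %d vertices, diameter %.3f m, area %.3f m^2\n",
              nrow(x$vertices), x$diameter, x$area))
  invisible(x)
}

#' Crown diameter
#'
#' Maximum spacing between paired convex-hull vertices — by convexity this
#' equals the maximum pairwise distance over all tree points.
#'
#' @param hull `convex_hull_2d` from [crown_hull()].
#' @return crown diameter, meters.
#' @export
crown_diameter <- function(hull) {
  if (is.null(hull$vertices) || nrow(hull$vertices) < 2) {
    abort("crown_diameter needs a hull with at least 2 vertices")
  }
  hull$diameter
}

#' Crown area
#'
#' Shoelace area of the crown convex hull.
#'
#' @param hull `convex_hull_2d` from [crown_hull()].
#' @return crown projection area, m^2.
#' @export
crown_area <- function(hull) {
  if (is.null(hull$vertices) || nrow(hull$vertices) < 3) return(0)
  shoelace_area(hull$vertices)
}

#' Morphometry table for a segmented scene
#'
#' Computes, per segmented tree, its location, height, DBH (and trunk
#' radius DBH/2), crown diameter and crown area, with availability flags.
#'
#' @param cloud point cloud with an integer tree-label column.
#' @param label_col name of the label column (`"tree"` for pipeline output,
#'   `"label"` for ground-truth clouds); ids < 0 are skipped.
#' @return tibble: `tree_id`, `x`, `y`, `n`, `height_m`, `dbh_m`,
#'   `radius_m`, `crown_diameter_m`, `crown_area_m2`, `flags`, and a `hull`
#'   list-column of `convex_hull_2d` objects (NULL where degenerate).
#' @export
extract_tree_parameters <- function(cloud, label_col = "tree") {
  lab <- cloud[[label_col]]
  if (is.null(lab)) abort(paste0("no '", label_col, "' column in cloud"))
  ids <- sort(unique(lab[!is.na(lab) & lab >= 0]))
  rows <- lapply(ids, function(id) {
    pts <- cloud[!is.na(lab) & lab == id, ]
    h <- tree_height(pts)
    d <- dbh(pts)
    hull <- tryCatch(crown_hull(pts), error = function(e) NULL)
    flags <- c(
      if (!d$available) "dbh_unavailable",
      if (is.null(hull)) "degenerate_crown"
    )
    loc <- if (d$available) c(d$fit$a, d$fit$b) else c(mean(pts$x), mean(pts$y))
    tibble::tibble(
      tree_id = id, x = loc[1], y = loc[2], n = nrow(pts),
      height_m = h, dbh_m = d$dbh, radius_m = d$dbh / 2,
      crown_diameter_m = if (is.null(hull)) NA_real_ else hull$diameter,
      crown_area_m2 = if (is.null(hull)) NA_real_ else hull$area,
      flags = paste(flags, collapse = ";"),
      hull = list(hull)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write the morphometry table as CSV
#'
#' Two-decimal output (heights and DBH to 0.01 m, areas to 0.01 m^2),
#' without the hull list-column.
#'
#' @param params output of [extract_tree_parameters()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_tree_csv <- function(params, path) {
  out <- params |>
    dplyr::select(-dplyr::any_of("hull")) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric) & !dplyr::any_of(c("tree_id", "n")),
                                ~ round(.x, 2)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
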