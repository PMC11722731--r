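# Topology checking: XOY footprint overlay merge of over-segmented
# fragments, and trunk Z-voxel skeletons for interference removal.

#' XOY footprint of a cluster
#'
#' Projects the cluster onto the horizontal plane and takes the 2D convex
#' hull. Degenerate projections (fewer than 3 distinct non-collinear XY
#' points) yield a zero-area footprint flagged `degenerate`, with the raw
#' XY points retained for the point-based overlap fallback.
#'
#' @param points cluster points (x, y, and optionally z).
#' @return object of class `footprint`: `vertices` (CCW matrix or NULL),
#'   `area` (m^2), `degenerate`, `xy` (projection of all member points).
#' @export
project_xoy <- function(points) {
  xy <- xy_of(points)
  hull <- tryCatch(quickhull(xy), error = function(e) NULL)
  if (is.null(hull)) {
    structure(list(vertices = NULL, area = 0, degenerate = TRUE, xy = xy),
              class = "footprint")
  } else {
    structure(list(vertices = hull, area = shoelace_area(hull),
                   degenerate = FALSE, xy = xy),
              class = "footprint")
  }
}

#' @export
print.footprint <- function(x, ...) {
  if (x$degenerate) cat("degenerate footprint of", nrow(x$xy), "points\n")
  else cat(sprintf("footprint: %d hull vertices, area %.3f m^2\n",
                   nrow(x$vertices), x$area))
  invisible(x)
}

#' Overlap measures between two XOY footprints
#'
#' `containment` is the intersection area over the smaller footprint's area
#' (1 when one footprint lies inside the other); `iou` is intersection over
#' union. When a footprint is degenerate, containment falls back to the
#' fraction of the degenerate footprint's points inside the other polygon.
#'
#' @param f1,f2 `footprint` objects from [project_xoy()].
#' @return tibble with columns `containment` and `iou`, both in \[0, 1\].
#' @export
footprint_overlap <- function(f1, f2) {
  if (f1$degenerate || f2$degenerate) {
    if (f1$degenerate && f2$degenerate) {
      return(tibble::tibble(containment = 0, iou = 0))
    }
    deg <- if (f1$degenerate) f1 else f2
    full <- if (f1$degenerate) f2 else f1
    frac <- mean(points_in_convex(deg$xy, full$vertices))
    return(tibble::tibble(containment = frac, iou = 0))
  }
  inter <- convex_intersection_area(f1$vertices, f2$vertices)
  uni <- f1$area + f2$area - inter
  tibble::tibble(
    containment = min(1, inter / min(f1$area, f2$area)),
    iou = if (uni > 0) min(1, inter / uni) else 0
  )
}

#' Merge over-segmented clusters by footprint containment
#'
#' Computes the XOY footprint of every cluster and transitively merges all
#' cluster pairs whose footprints "completely overlap": containment of the
#' smaller footprint at or above `containment_cutoff` (default 0.9, which
#' tolerates hull jitter from sparse fragments while leaving genuinely
#' adjacent crowns apart). The transitive closure is taken with union-find,
#' so three mutually contained fragments collapse to one cluster. The
#' operation conserves points and is idempotent.
#'
#' @param cloud clustered point cloud.
#' @param containment_cutoff merge threshold on footprint containment.
#' @return the cloud with merged `cluster` ids (the smallest id of each
#'   merged group survives). The old-to-new id map is attached as attribute
#'   `"merge_map"` (tibble old, new).
#' @export
merge_oversegmented <- function(cloud, containment_cutoff = 0.9) {
  ids <- sort(unique(cloud$cluster[!is.na(cloud$cluster)]))
  k <- length(ids)
  if (k <= 1) {
    attr(cloud, "merge_map") <- tibble::tibble(old = ids, new = ids)
    return(cloud)
  }
  fps <- lapply(ids, function(id) {
    project_xoy(cloud[!is.na(cloud$cluster) & cloud$cluster == id, ])
  })

  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      ov <- footprint_overlap(fps[[i]], fps[[j]])
      if (ov$containment >= containment_cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  new_ids <- ids[roots]
  map <- tibble::tibble(old = ids, new = new_ids)
  idx <- match(cloud$cluster, ids)
  cloud$cluster <- ifelse(is.na(idx), NA_integer_, new_ids[idx])
  attr(cloud, "merge_map") <- map
  cloud
}

#' Trunk growth skeleton from Z-axis voxels
#'
#' Slices the cluster into contiguous horizontal slabs of `slab_height` and
#' records each slab's point count and XY centroid. The skeleton axis is the
#' coordinate-wise median of the centroids of the below-crown (trunk) slabs.
#' The crown base is estimated from the count profile: starting at the
#' fullest slab (certainly crown), walk downward while counts stay above
#' `stem_mult` times the bare-stem reference (the median count of the
#' lowest occupied slabs); the walk stops where foliage returns fade into
#' stem-level counts. Anchoring at the maximum keeps the estimate robust
#' for slender crowns whose per-slab counts never spike far above a dense
#' stem's, and street furniture part-way up the stem cannot capture the
#' walk because clean stem slabs separate it from the crown.
#'
#' @param points cluster points (x, y, z).
#' @param slab_height slab thickness in meters (default 0.25).
#' @param stem_mult multiplier on the bare-stem slab count above which a
#'   slab still counts as crown during the downward walk.
#' @return object of class `trunk_skeleton`: a tibble of slabs (`z_lo`,
#'   `z_hi`, `n`, `cx`, `cy`, `occupied`) with attributes `slab_height`,
#'   `axis` (XY), `crown_base`, and `available`. Clusters shorter than two
#'   slabs return `available = FALSE`.
#' @export
build_trunk_skeleton <- function(points, slab_height = 0.25, stem_mult = 1.2) {
  pts <- as_point_cloud(points)
  if (nrow(pts) == 0 || diff(range(pts$z)) < 2 * slab_height) {
    out <- tibble::tibble(z_lo = double(), z_hi = double(), n = integer(),
                          cx = double(), cy = double(), occupied = logical())
    attr(out, "available") <- FALSE
    class(out) <- c("trunk_skeleton", class(out))
    return(out)
  }
  z0 <- min(pts$z)
  n_slab <- ceiling((max(pts$z) - z0) / slab_height)
  bin <- pmin(pmax(floor((pts$z - z0) / slab_height) + 1L, 1L), n_slab)
  tab <- tabulate(bin, n_slab)
  cx <- vapply(seq_len(n_slab), function(i) if (tab[i] > 0) mean(pts$x[bin == i]) else NA_real_, 0)
  cy <- vapply(seq_len(n_slab), function(i) if (tab[i] > 0) mean(pts$y[bin == i]) else NA_real_, 0)
  out <- tibble::tibble(
    z_lo = z0 + (seq_len(n_slab) - 1) * slab_height,
    z_hi = z0 + seq_len(n_slab) * slab_height,
    n = tab, cx = cx, cy = cy, occupied = tab > 0L
  )

  occ <- which(out$occupied)
  ref <- median(out$n[occ[seq_len(min(4, length(occ)))]])
  j <- which.max(out$n)
  while (j > 1 && out$n[j - 1] > stem_mult * ref) j <- j - 1
  crown_base <- out$z_lo[j]
  trunk_slabs <- out$occupied & out$z_hi <= crown_base
  axis <- if (any(trunk_slabs)) {
    c(median(out$cx[trunk_slabs]), median(out$cy[trunk_slabs]))
  } else c(median(pts$x), median(pts$y))

  attr(out, "available") <- TRUE
  attr(out, "slab_height") <- slab_height
  attr(out, "axis") <- axis
  attr(out, "crown_base") <- crown_base
  class(out) <- c("trunk_skeleton", class(out))
  out
}

#' Strip pole-like interference hugging a trunk
#'
#' Uses the trunk growth skeleton to decide whether anything foreign clings
#' to the stem: a below-crown slab whose XY centroid deviates more than
#' `dev_min` from the trunk axis is contaminated (signs, e-bikes, parked
#' vehicles pull the centroid sideways — the stem alone cannot). When
#' contamination is found, all points below the top of the contaminated
#' zone (plus one slab of margin, capped at the crown base) that lie
#' farther than `radius_cutoff` from the axis are rejected. A clean stem
#' rejects nothing, and nothing above the crown base is ever touched. The
#' pipeline's default cutoff is twice the fitted breast-height radius plus
#' 0.2 m, i.e. just beyond the stem surface.
#'
#' @param points cluster points.
#' @param skeleton `trunk_skeleton` for the cluster (supplies slabs, axis
#'   and crown base).
#' @param radius_cutoff XY distance from the axis beyond which points in
#'   the contaminated zone are rejected, meters.
#' @param axis optional XY axis override (e.g. a breast-height circle-fit
#'   center, which is more accurate than slab centroids).
#' @param crown_base optional crown-base override, meters (absolute z).
#' @param dev_min centroid deviation flagging a slab as contaminated, m.
#' @return list with `tree` (retained points tibble) and `rejected` (row
#'   indices into `points` that were stripped).
#' @export
remove_interference <- function(points, skeleton = NULL, radius_cutoff,
                                axis = NULL, crown_base = NULL,
                                dev_min = 0.08) {
  pts <- as_point_cloud_keep(points)
  skel_ok <- !is.null(skeleton) && isTRUE(attr(skeleton, "available"))
  if (is.null(axis)) {
    if (!skel_ok) abort("remove_interference needs a skeleton or an explicit axis")
    axis <- attr(skeleton, "axis")
  }
  if (is.null(crown_base)) {
    crown_base <- if (skel_ok) attr(skeleton, "crown_base") else -Inf
  }
  none <- list(tree = pts, rejected = integer(0))
  if (!skel_ok) return(none)

  below <- skeleton$occupied & skeleton$z_hi <= crown_base
  dev <- sqrt((skeleton$cx - axis[1])^2 + (skeleton$cy - axis[2])^2)
  contaminated <- below & !is.na(dev) & dev > dev_min
  if (!any(contaminated)) return(none)

  ceiling_z <- min(crown_base,
                   max(skeleton$z_hi[contaminated]) + attr(skeleton, "slab_height"))
  d <- sqrt((pts$x - axis[1])^2 + (pts$y - axis[2])^2)
  keep <- pts$z >= ceiling_z | d <= radius_cutoff
  list(tree = pts[keep, , drop = FALSE], rejected = which(!keep))
}
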