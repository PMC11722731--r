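# End-to-end segmentation pipeline and its configuration.

seg_defaults <- function() {
  list(
    ground = list(enabled = FALSE, cell = 1, height_margin = 0.3),
    dbscan = list(eps = 0.6, min_pts = 10),
    ransac = list(dist_threshold = 0.4, n_iter = 200, seed = 1L),
    noise = list(linear_ratio_cutoff = 0.9, exempt_linear = TRUE),
    merge = list(containment_cutoff = 0.9),
    skeleton = list(slab_height = 0.25, stem_mult = 1.2, radius_margin = 0.2),
    slab = list(lo = 1.25, hi = 1.35, linkage = 0.35, min_pts = 10,
                arc_min = 180, rms_rel = 0.25),
    trunk = list(r_min = 0.03, r_max = 1.5),
    split = list(voxel_width = 0.5),
    seed = 1L
  )
}

#' Pipeline configuration
#'
#' Builds a validated configuration for [segment_trees()]. Overrides use
#' dotted keys, e.g. `seg_config("dbscan.eps" = 0.5, "trunk.r_max" = 2.5)`.
#' Unknown keys are rejected. Defaults: DBSCAN eps 0.6 m / min_pts 10,
#' RANSAC inlier distance 0.4 m, linearity cutoff 0.9, footprint containment
#' cutoff 0.9, skeleton slabs 0.25 m, breast-height slab 1.25-1.35 m, trunk
#' radius gate \[0.03, 1.5\] m, split voxel 0.5 m.
#'
#' @param ... dotted-key overrides (see above).
#' @return nested configuration list of class `seg_config`.
#' @export
seg_config <- function(...) {
  cfg <- seg_defaults()
  dots <- list(...)
  if (length(dots) > 0 && (is.null(names(dots)) || any(names(dots) == ""))) {
    abort("seg_config overrides must be named, e.g. 'dbscan.eps' = 0.5")
  }
  for (key in names(dots)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1 && parts == "seed") {
      cfg$seed <- as.integer(dots[[key]])
      next
    }
    if (length(parts) != 2 || is.null(cfg[[parts[1]]]) ||
        !(parts[2] %in% names(cfg[[parts[1]]]))) {
      abort(paste0("unknown configuration key: ", key))
    }
    cfg[[parts[1]]][[parts[2]]] <- dots[[key]]
  }
  with(cfg, {
    stopifnot(dbscan$eps > 0, dbscan$min_pts >= 1,
              ransac$dist_threshold > 0, ransac$n_iter >= 1,
              noise$linear_ratio_cutoff > 0, noise$linear_ratio_cutoff <= 1,
              merge$containment_cutoff > 0, merge$containment_cutoff <= 1,
              skeleton$slab_height > 0, slab$lo < slab$hi,
              trunk$r_min > 0, trunk$r_min < trunk$r_max,
              split$voxel_width > 0)
  })
  structure(cfg, class = "seg_config")
}

#' Segment individual street trees from an MLS point cloud
#'
#' The full hierarchical pipeline: optional grid-minimum ground removal;
#' DBSCAN pre-segmentation; RANSAC linearity classification and the
#' one-third-of-average noise filter; XOY footprint topology merge of
#' over-segmented fragments; discarding of purely pole-like (all-linear,
#' unmerged) clusters; breast-height circle-fit localization; density-valley
#' voxel split of clusters holding several trunks; and per-tree
#' trunk-skeleton interference removal (cutoff 2 x fitted breast-height
#' radius + margin). Clusters in which no plausible trunk can be located
#' are returned to noise.
#'
#' @param cloud point-cloud tibble.
#' @param config a [seg_config()] object.
#' @return object of class `tree_segmentation`:
#'   * `cloud` — the (possibly ground-filtered) cloud with an integer
#'     `tree` column: ids 0..k-1 dense in order of increasing x, -1 noise;
#'   * `trees` — tibble `tree_id`, `x`, `y` (breast-height fit center),
#'     `r_bh` (fitted trunk radius), `n`;
#'   * `stages` — per-stage cluster/point bookkeeping;
#'   * `config` — the resolved configuration.
#' @export
segment_trees <- function(cloud, config = seg_config()) {
  stopifnot(inherits(config, "seg_config"))
  cloud <- as_point_cloud_keep(cloud)
  if (nrow(cloud) == 0) abort("segment_trees: empty cloud")
  log_rows <- list()
  note <- function(stage, clusters, points) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      stage = stage, clusters = clusters, points = points)
  }

  if (isTRUE(config$ground$enabled)) {
    cloud <- remove_ground(cloud, config$ground$cell, config$ground$height_margin)
  }
  note("input", NA_integer_, nrow(cloud))

  cloud <- dbscan_cluster(cloud, config$dbscan$eps, config$dbscan$min_pts)
  note("dbscan", dplyr::n_distinct(cloud$cluster, na.rm = TRUE),
       sum(!is.na(cloud$cluster)))

  classes <- classify_clusters(
    cloud, linear_ratio_cutoff = config$noise$linear_ratio_cutoff,
    dist_threshold = config$ransac$dist_threshold,
    n_iter = config$ransac$n_iter, seed = config$ransac$seed
  )
  classes <- filter_noise_clusters(classes, config$noise$exempt_linear)
  cloud <- apply_retention(cloud, classes)
  note("noise_filter", sum(classes$retained), sum(!is.na(cloud$cluster)))

  cloud <- merge_oversegmented(cloud, config$merge$containment_cutoff)
  merge_map <- attr(cloud, "merge_map")
  note("merge", dplyr::n_distinct(cloud$cluster, na.rm = TRUE),
       sum(!is.na(cloud$cluster)))

  # clusters whose every fragment is linear are pole-like interference
  kinds <- classes |>
    dplyr::filter(.data$retained) |>
    dplyr::left_join(merge_map, by = c(cluster = "old")) |>
    dplyr::group_by(.data$new) |>
    dplyr::summarise(any_nonlinear = any(.data$kind == "nonlinear"))
  pole_like <- kinds$new[!kinds$any_nonlinear]
  cloud$cluster[cloud$cluster %in% pole_like] <- NA_integer_
  note("drop_pole_like", dplyr::n_distinct(cloud$cluster, na.rm = TRUE),
       sum(!is.na(cloud$cluster)))

  fits <- locate_trees(
    cloud, lo = config$slab$lo, hi = config$slab$hi,
    linkage = config$slab$linkage, r_min = config$trunk$r_min,
    r_max = config$trunk$r_max, min_slab_pts = config$slab$min_pts,
    arc_min = config$slab$arc_min, rms_rel = config$slab$rms_rel
  )
  located_ids <- unique(fits$cluster)
  all_ids <- unique(cloud$cluster[!is.na(cloud$cluster)])
  cloud$cluster[cloud$cluster %in% setdiff(all_ids, located_ids)] <- NA_integer_
  note("locate", length(located_ids), sum(!is.na(cloud$cluster)))

  # split clusters holding several trunks, then strip trunk-hugging
  # interference per located tree
  tree_rows <- list()
  tree_assign <- rep(NA_integer_, nrow(cloud))
  next_tree <- 0L
  for (id in located_ids) {
    f <- fits[fits$cluster == id, ]
    idx <- which(!is.na(cloud$cluster) & cloud$cluster == id)
    pts <- cloud[idx, ]
    if (detect_undersegmentation(f)) {
      al <- align_to_trunk_axis(pts, f[, c("x", "y")])
      ctr_sorted <- f[order(as.vector(
        (as.matrix(f[, c("x", "y")]) -
           matrix(al$origin, nrow(f), 2, byrow = TRUE)) %*% al$rotation[1, ])), ]
      plan <- find_boundary_voxel(al$uv[, 1], al$centers_u,
                                  config$split$voxel_width)
      parts <- findInterval(al$uv[, 1], sort(plan$boundaries)) + 1L
    } else {
      ctr_sorted <- f
      parts <- rep(1L, nrow(pts))
    }
    for (p in seq_len(nrow(ctr_sorted))) {
      pidx <- idx[parts == p]
      fit_p <- ctr_sorted[p, ]
      cutoff <- 2 * fit_p$r + config$skeleton$radius_margin
      child <- cloud[pidx, ]
      skel <- build_trunk_skeleton(child, config$skeleton$slab_height,
                                   config$skeleton$stem_mult)
      ri <- remove_interference(
        child, skeleton = if (isTRUE(attr(skel, "available"))) skel else NULL,
        radius_cutoff = cutoff, axis = c(fit_p$x, fit_p$y),
        crown_base = if (isTRUE(attr(skel, "available"))) NULL else -Inf
      )
      keep <- setdiff(seq_along(pidx), ri$rejected)
      tree_assign[pidx[keep]] <- next_tree
      tree_rows[[length(tree_rows) + 1]] <- tibble::tibble(
        tree_id = next_tree, x = fit_p$x, y = fit_p$y, r_bh = fit_p$r,
        n = length(keep)
      )
      next_tree <- next_tree + 1L
    }
  }
  trees <- dplyr::bind_rows(tree_rows)
  if (nrow(trees) == 0) {
    warn("no trees located in the scene")
    trees <- tibble::tibble(tree_id = integer(), x = double(), y = double(),
                            r_bh = double(), n = integer())
  } else {
    # renumber 0..k-1 by increasing x for stable, readable output
    ord <- order(trees$x, trees$y)
    remap <- integer(nrow(trees))
    remap[trees$tree_id[ord] + 1L] <- seq_along(ord) - 1L
    tree_assign <- ifelse(is.na(tree_assign), NA_integer_,
                          remap[tree_assign + 1L])
    trees <- trees[ord, ]
    trees$tree_id <- seq_len(nrow(trees)) - 1L
  }
  note("trees", nrow(trees), sum(!is.na(tree_assign)))

  cloud$tree <- ifelse(is.na(tree_assign), -1L, tree_assign)
  cloud$cluster <- NULL
  structure(
    list(cloud = cloud, trees = trees,
         stages = dplyr::bind_rows(log_rows), config = config),
    class = "tree_segmentation"
  )
}

#' @export
print.tree_segmentation <- function(x, ...) {
  cat(sprintf("tree segmentation: %d trees from %d points\n",
              nrow(x$trees), nrow(x$cloud)))
  print(x$stages)
  invisible(x)
}
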