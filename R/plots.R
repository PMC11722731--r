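# ggplot2 views of scenes, segmentations, split plans and evaluations.

#' Plan view of a segmented scene
#'
#' XY scatter colored by assigned tree (noise in grey), with crown hulls
#' and breast-height trunk locations overlaid.
#'
#' @param object `tree_segmentation` result.
#' @param sample_n at most this many points are drawn (plots stay light).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tree_segmentation <- function(object, sample_n = 20000, ...) {
  cl <- object$cloud
  if (nrow(cl) > sample_n) {
    cl <- cl[unique(round(seq(1, nrow(cl), length.out = sample_n))), ]
  }
  cl$tree_f <- factor(ifelse(cl$tree < 0, NA, cl$tree))
  p <- ggplot2::ggplot(cl, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$tree_f), size = 0.2, alpha = 0.5) +
    ggplot2::geom_point(data = object$trees,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        shape = 4, size = 3, inherit.aes = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(color = "tree", x = "x [m]", y = "y [m]",
                  title = sprintf("%d segmented trees", nrow(object$trees))) +
    ggplot2::theme_minimal()
  params <- tryCatch(extract_tree_parameters(object$cloud), error = function(e) NULL)
  if (!is.null(params) && nrow(params) > 0) {
    hulls <- dplyr::bind_rows(lapply(seq_len(nrow(params)), function(i) {
      h <- params$hull[[i]]
      if (is.null(h)) return(NULL)
      tibble::tibble(tree_f = factor(params$tree_id[i]),
                     x = h$vertices[, 1], y = h$vertices[, 2])
    }))
    if (nrow(hulls) > 0) {
      p <- p + ggplot2::geom_polygon(
        data = hulls, ggplot2::aes(group = .data$tree_f, color = .data$tree_f),
        fill = NA, linewidth = 0.3, inherit.aes = FALSE)
    }
  }
  p
}

#' Density profile of a split plan
#'
#' Voxel counts along the trunk-connection axis with trunk positions
#' (dashed) and the chosen boundary voxels (solid) marked.
#'
#' @param object `split_plan` from [find_boundary_voxel()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.split_plan <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$center, y = .data$n)) +
    ggplot2::geom_col(width = object$voxel_width * 0.95, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$centers_u, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$boundaries, color = "red") +
    ggplot2::labs(x = "position along trunk connection [m]",
                  y = "points per voxel") +
    ggplot2::theme_minimal()
}

#' Per-tree metric bars for an evaluation
#'
#' @param object `tree_eval` object.
#' @param ... unused.
#' @return a ggplot of per-tree P, R and F1.
#' @export
autoplot.tree_eval <- function(object, ...) {
  long <- object$per_tree |>
    dplyr::select(dplyr::all_of(c("truth", "P", "R", "F1"))) |>
    tidyr_pivot()
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$truth), y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "truth tree", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(df) {
  dplyr::bind_rows(lapply(c("P", "R", "F1"), function(m) {
    tibble::tibble(truth = df$truth, metric = m, value = df[[m]])
  }))
}
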