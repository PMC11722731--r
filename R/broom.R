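# tidy()/glance() methods for the package's fitted objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a breast-height circle fit
#' @param x `circle_fit` object.
#' @param ... unused.
#' @return one-row tibble: `a`, `b`, `r`, `dbh`, `rms_residual`, `n_points`.
#' @export
tidy.circle_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, r = x$r, dbh = 2 * x$r,
                 rms_residual = x$rms_residual, n_points = x$n_points)
}

#' @rdname tidy.circle_fit
#' @export
glance.circle_fit <- function(x, ...) {
  tibble::tibble(rms_residual = x$rms_residual, n_points = x$n_points)
}

#' Tidy a RANSAC line fit
#' @param x `line_ransac` object.
#' @param ... unused.
#' @return one-row tibble with the line anchor, direction and inlier ratio.
#' @export
tidy.line_ransac <- function(x, ...) {
  tibble::tibble(
    x0 = x$point[1], y0 = x$point[2], z0 = x$point[3],
    dx = x$direction[1], dy = x$direction[2], dz = x$direction[3],
    inlier_ratio = x$inlier_ratio, n_inliers = x$n_inliers, n = x$n
  )
}

#' Tidy a segmentation result
#' @param x `tree_segmentation` object.
#' @param ... unused.
#' @return the per-tree table (`tree_id`, `x`, `y`, `r_bh`, `n`).
#' @export
tidy.tree_segmentation <- function(x, ...) x$trees

#' @rdname tidy.tree_segmentation
#' @export
glance.tree_segmentation <- function(x, ...) {
  tibble::tibble(
    n_trees = nrow(x$trees),
    n_points = nrow(x$cloud),
    n_assigned = sum(x$cloud$tree >= 0),
    noise_fraction = mean(x$cloud$tree < 0)
  )
}

#' Tidy an evaluation report
#' @param x `tree_eval` object.
#' @param ... unused.
#' @return the per-tree metric table.
#' @export
tidy.tree_eval <- function(x, ...) x$per_tree

#' @rdname tidy.tree_eval
#' @export
glance.tree_eval <- function(x, ...) {
  v <- x$verdict_counts
  tibble::tibble(
    P = x$averages$P, R = x$averages$R, F1 = x$averages$F1,
    AIoU = x$averages$AIoU, n_pred = x$n_pred, n_truth = x$n_truth,
    trees_tp = as.integer(v["tp"]), trees_tn = as.integer(v["tn"]),
    trees_fp = as.integer(v["fp"])
  )
}

#' Generic tidiers
#'
#' `tidy()` and `glance()` generics (broom-compatible; defined here so the
#' package stands alone).
#' @param x object to tidy.
#' @param ... method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
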