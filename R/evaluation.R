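# Point- and tree-oriented evaluation of a segmentation against ground
# truth: precision, recall, F1, crown-area IoU, and the 80%/50% tree-level
# detection rule.

#' Match predicted trees to ground-truth trees by maximum overlap
#'
#' Greedy matching on shared point counts: prediction/truth pairs are taken
#' in decreasing overlap, each truth tree receives at most one prediction
#' and vice versa. Noise ids (< 0, NA) on either side never match.
#'
#' @param pred_labels integer predicted tree ids per point (-1/NA noise).
#' @param truth_labels integer ground-truth tree ids per point, same length.
#' @return tibble `pred`, `truth`, `overlap` — one row per matched pair.
#' @export
match_trees <- function(pred_labels, truth_labels) {
  if (length(pred_labels) != length(truth_labels)) {
    abort("label arrays differ in length")
  }
  ok <- !is.na(pred_labels) & !is.na(truth_labels) &
    pred_labels >= 0 & truth_labels >= 0
  if (!any(ok)) {
    return(tibble::tibble(pred = integer(), truth = integer(), overlap = integer()))
  }
  tab <- tibble::tibble(pred = pred_labels[ok], truth = truth_labels[ok]) |>
    dplyr::count(.data$pred, .data$truth, name = "overlap") |>
    dplyr::arrange(dplyr::desc(.data$overlap))
  used_p <- integer(); used_t <- integer()
  keep <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!(tab$pred[i] %in% used_p) && !(tab$truth[i] %in% used_t)) {
      keep[i] <- TRUE
      used_p <- c(used_p, tab$pred[i])
      used_t <- c(used_t, tab$truth[i])
    }
  }
  tab[keep, ]
}

#' Precision, recall and F1 from confusion counts
#'
#' P = tp / (tp + fp); R = tp / (tp + tn), where `tn` here counts the truth
#' points the prediction missed (the field often writes fn; the symbol is
#' kept for parity with the evaluation tables this mirrors); F1 is their
#' harmonic mean. Undefined ratios (zero denominators) come back NA.
#'
#' @param tp,fp,tn non-negative counts (vectorized).
#' @return tibble with columns `P`, `R`, `F1`.
#' @export
point_metrics <- function(tp, fp, tn) {
  P <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  R <- ifelse(tp + tn > 0, tp / (tp + tn), NA_real_)
  F1 <- ifelse(!is.na(P) & !is.na(R) & (P + R) > 0, 2 * P * R / (P + R), NA_real_)
  tibble::tibble(P = P, R = R, F1 = F1)
}

#' Tree-level detection verdicts (80%/50% rule)
#'
#' A truth tree with more than 80% of its points captured by its matched
#' prediction is correctly segmented (`tp`); below 50% it is missed (`fp`);
#' the 50–80% band is the intermediate verdict (`tn`).
#'
#' @param overlap_fractions per truth tree, fraction of its points captured
#'   by its matched prediction, in \[0, 1\].
#' @return character vector of verdicts in `c("tp", "fp", "tn")`.
#' @export
tree_level_verdicts <- function(overlap_fractions) {
  stopifnot(all(overlap_fractions >= 0 & overlap_fractions <= 1))
  ifelse(overlap_fractions > 0.8, "tp",
         ifelse(overlap_fractions < 0.5, "fp", "tn"))
}

#' Crown-area intersection over union
#'
#' Area IoU between two convex crown polygons (predicted vs reference).
#'
#' @param polyA,polyB convex polygons: `convex_hull_2d` objects, `footprint`
#'   objects, or plain CCW vertex matrices.
#' @return IoU in \[0, 1\]; NA when both polygons have zero area.
#' @export
aiou <- function(polyA, polyB) {
  pa <- poly_vertices(polyA); pb <- poly_vertices(polyB)
  aa <- shoelace_area(pa); ab <- shoelace_area(pb)
  if (aa == 0 && ab == 0) return(NA_real_)
  inter <- convex_intersection_area(pa, pb)
  inter / (aa + ab - inter)
}

poly_vertices <- function(p) {
  if (inherits(p, "convex_hull_2d")) p$vertices
  else if (inherits(p, "footprint")) p$vertices
  else as.matrix(p)
}

#' Evaluate a segmentation against ground-truth labels
#'
#' Matches predicted to truth trees by maximum overlap, then per truth tree
#' computes point-level confusion counts and P/R/F1, the crown-area IoU of
#' the predicted vs truth crown hulls, and the 80%/50% detection verdict.
#' Truth points labeled < 0 (noise, ground, distractors) are excluded from
#' all per-tree denominators; false positives count predicted points that
#' belong to a different truth tree.
#'
#' @param pred_labels predicted per-point tree ids (-1/NA = unassigned).
#' @param truth_labels ground-truth per-point tree ids (same length).
#' @param cloud optional point cloud (x, y) aligned with the labels; when
#'   given, per-tree crown-area IoU is computed from the XY hulls.
#' @return object of class `tree_eval`: `per_tree` tibble (`truth`, `pred`,
#'   `tp`, `fp`, `tn`, `P`, `R`, `F1`, `capture`, `verdict`, `aiou`),
#'   `averages` (unweighted scene means), and counts of predicted/truth
#'   trees.
#' @export
evaluate_segmentation <- function(pred_labels, truth_labels, cloud = NULL) {
  matches <- match_trees(pred_labels, truth_labels)
  truth_ids <- sort(unique(truth_labels[!is.na(truth_labels) & truth_labels >= 0]))
  pred_ok <- !is.na(pred_labels) & pred_labels >= 0
  truth_ok <- !is.na(truth_labels) & truth_labels >= 0

  rows <- lapply(truth_ids, function(ti) {
    pi <- matches$pred[matches$truth == ti]
    n_truth <- sum(truth_labels == ti, na.rm = TRUE)
    if (length(pi) == 0) {
      counts <- tibble::tibble(tp = 0L, fp = 0L, tn = n_truth)
      pi <- NA_integer_
    } else {
      in_pred <- pred_ok & pred_labels == pi
      tp <- sum(in_pred & truth_labels == ti, na.rm = TRUE)
      fp <- sum(in_pred & truth_ok & truth_labels != ti, na.rm = TRUE)
      tn <- n_truth - tp
      counts <- tibble::tibble(tp = tp, fp = fp, tn = tn)
    }
    iou <- NA_real_
    if (!is.null(cloud) && !is.na(pi)) {
      ha <- tryCatch(crown_hull(cloud[pred_ok & pred_labels == pi, ]),
                     error = function(e) NULL)
      hb <- tryCatch(crown_hull(cloud[truth_labels == ti & truth_ok, ]),
                     error = function(e) NULL)
      if (!is.null(ha) && !is.null(hb)) iou <- aiou(ha, hb)
    }
    dplyr::bind_cols(
      tibble::tibble(truth = ti, pred = pi), counts,
      point_metrics(counts$tp, counts$fp, counts$tn),
      tibble::tibble(capture = counts$tp / n_truth, aiou = iou)
    )
  })
  per_tree <- dplyr::bind_rows(rows)
  per_tree$verdict <- tree_level_verdicts(per_tree$capture)

  averages <- list(
    P = mean(per_tree$P, na.rm = TRUE),
    R = mean(per_tree$R, na.rm = TRUE),
    F1 = mean(per_tree$F1, na.rm = TRUE),
    AIoU = if (all(is.na(per_tree$aiou))) NA_real_ else mean(per_tree$aiou, na.rm = TRUE)
  )
  structure(
    list(per_tree = per_tree, averages = averages,
         n_pred = length(unique(pred_labels[pred_ok])),
         n_truth = length(truth_ids),
         verdict_counts = table(factor(per_tree$verdict, c("tp", "tn", "fp")))),
    class = "tree_eval"
  )
}

#' @export
print.tree_eval <- function(x, ...) {
  cat(sprintf("segmentation evaluation: %d predicted vs %d truth trees\n",
              x$n_pred, x$n_truth))
  cat(sprintf("  scene means: P %.4f  R %.4f  F1 %.4f%s\n",
              x$averages$P, x$averages$R, x$averages$F1,
              if (is.na(x$averages$AIoU)) "" else sprintf("  AIoU %.4f", x$averages$AIoU)))
  v <- x$verdict_counts
  cat(sprintf("  tree verdicts: %d tp, %d tn, %d fp\n", v["tp"], v["tn"], v["fp"]))
  invisible(x)
}

#' Write an evaluation report to CSV and JSON
#'
#' @param eval `tree_eval` object.
#' @param csv_path per-tree table destination (percent metrics, 2 decimals).
#' @param json_path optional scene-summary JSON destination.
#' @return `csv_path`, invisibly.
#' @export
write_eval_report <- function(eval, csv_path, json_path = NULL) {
  tab <- eval$per_tree |>
    dplyr::mutate(
      P = round(100 * .data$P, 2), R = round(100 * .data$R, 2),
      F1 = round(100 * .data$F1, 2),
      aiou = round(100 * .data$aiou, 2)
    )
  utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort("jsonlite is needed to write the JSON summary")
    }
    jsonlite::write_json(
      c(eval$averages,
        list(n_pred = eval$n_pred, n_truth = eval$n_truth,
             verdicts = as.list(eval$verdict_counts))),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(csv_path)
}
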