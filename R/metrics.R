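# Evaluation metrics for plant-image segmentation: whole-image pixel
# accuracy, fruit pixel accuracy, and the fruit over- and
# under-segmentation rates.
#
#   Acc_seg   = k / (m n)                    k matching pixels, m x n image
#   Acc_fruit = l_fruit / a                  a ground-truth fruit pixels
#   Seg_over  = P_over  / (P_gt + P_over)    spurious fruit pixels
#   Seg_under = P_under / (P_gt + P_over)    missed fruit pixels
#
# Both rates share the denominator P_gt + P_over. Predictions and ground
# truth are compared in role space (fruit / leaf / background), never by
# raw cluster index.

check_same_dim <- function(a, b) {
  if (!all(dim(a) == dim(b))) {
    stop("invalid input: prediction and ground truth have different extents",
         call. = FALSE)
  }
}

#' Whole-image segmentation accuracy
#'
#' Fraction of pixels whose role (fruit / leaf / background) matches the
#' ground truth.
#'
#' @param pred_labels,gt_labels Integer H x W label matrices.
#' @param pred_roles,gt_roles Named role vectors (see [assign_roles()])
#'   mapping each side's class indices to roles.
#' @return The accuracy in `[0, 1]`.
#' @export
acc_seg <- function(pred_labels, pred_roles, gt_labels, gt_roles) {
  check_same_dim(pred_labels, gt_labels)
  mean(role_codes(pred_labels, pred_roles) == role_codes(gt_labels, gt_roles))
}

#' Fruit segmentation accuracy
#'
#' `l_fruit / a`, where `a` is the number of ground-truth fruit pixels and
#' `l_fruit` the number of those predicted as fruit.
#'
#' @param pred_mask,gt_mask Logical H x W fruit masks.
#' @return The accuracy in `[0, 1]`.
#' @export
acc_fruit <- function(pred_mask, gt_mask) {
  check_same_dim(pred_mask, gt_mask)
  a <- sum(gt_mask)
  if (a == 0L) {
    stop("undefined metric: the ground truth contains no fruit pixels", call. = FALSE)
  }
  sum(pred_mask & gt_mask) / a
}

#' Fruit over- and under-segmentation rates
#'
#' `P_over` counts fruit pixels present in the prediction but absent from
#' the ground truth; `P_under` counts ground-truth fruit pixels absent from
#' the prediction; both rates are normalized by `P_gt + P_over`.
#'
#' @param pred_mask,gt_mask Logical H x W fruit masks.
#' @return Named numeric vector `c(seg_over = ..., seg_under = ...)`.
#' @export
seg_rates <- function(pred_mask, gt_mask) {
  check_same_dim(pred_mask, gt_mask)
  p_gt <- sum(gt_mask)
  p_over <- sum(pred_mask & !gt_mask)
  p_under <- sum(!pred_mask & gt_mask)
  if (p_gt + p_over == 0L) {
    stop("undefined metric: no fruit pixels in either prediction or ground truth",
         call. = FALSE)
  }
  c(seg_over = p_over / (p_gt + p_over), seg_under = p_under / (p_gt + p_over))
}

fruit_mask <- function(labels, roles) role_codes(labels, roles) == 3L

#' Evaluate a segmentation against ground truth
#'
#' Computes all four metrics plus their raw pixel counts, aligning both
#' sides through their role assignments. Metrics whose denominator is empty
#' (no fruit anywhere) are reported as `NA`.
#'
#' @param pred A `segmentation_result` (from [segment_single()] or
#'   [segment_multiresolution()]) or an integer label matrix.
#' @param gt A `synthetic_scene` (from [generate_scene()]) or an integer
#'   label matrix.
#' @param pred_roles,gt_roles Role vectors; taken from the objects when
#'   omitted.
#' @return An object of class `metrics_report`: a list with `acc_seg`,
#'   `acc_fruit`, `seg_over`, `seg_under` and the counts `k_matching`, `m`,
#'   `n`, `l_fruit`, `a`, `p_gt`, `p_over`, `p_under`.
#' @export
evaluate_segmentation <- function(pred, gt, pred_roles = NULL, gt_roles = NULL) {
  if (inherits(pred, "segmentation_result")) {
    if (is.null(pred_roles)) pred_roles <- pred$roles
    pred <- pred$labels
  }
  if (inherits(gt, "synthetic_scene")) {
    if (is.null(gt_roles)) gt_roles <- gt$roles
    gt <- gt$labels
  }
  if (is.null(pred_roles) || is.null(gt_roles)) {
    stop("invalid input: role assignments are required for both sides", call. = FALSE)
  }
  check_same_dim(pred, gt)
  pr <- role_codes(pred, pred_roles)
  gr <- role_codes(gt, gt_roles)
  k_matching <- sum(pr == gr)
  pm <- pr == 3L; gm <- gr == 3L
  a <- sum(gm)
  l_fruit <- sum(pm & gm)
  p_over <- sum(pm & !gm)
  p_under <- sum(!pm & gm)
  denom <- a + p_over
  structure(list(
    acc_seg = k_matching / length(pr),
    acc_fruit = if (a > 0L) l_fruit / a else NA_real_,
    seg_over = if (denom > 0L) p_over / denom else NA_real_,
    seg_under = if (denom > 0L) p_under / denom else NA_real_,
    k_matching = k_matching, m = ncol(pred), n = nrow(pred),
    l_fruit = l_fruit, a = a, p_gt = a, p_over = p_over, p_under = p_under
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Segmentation metrics (%d x %d pixels)\n", x$n, x$m))
  cat(sprintf("  Acc_seg   = %.4f  (%d / %d)\n", x$acc_seg, x$k_matching, x$m * x$n))
  if (is.na(x$acc_fruit)) {
    cat("  Acc_fruit = NA (no ground-truth fruit)\n")
  } else {
    cat(sprintf("  Acc_fruit = %.4f  (%d / %d)\n", x$acc_fruit, x$l_fruit, x$a))
  }
  if (!is.na(x$seg_over)) {
    cat(sprintf("  Seg_over  = %.4f   Seg_under = %.4f  (P_gt %d, P_over %d, P_under %d)\n",
                x$seg_over, x$seg_under, x$p_gt, x$p_over, x$p_under))
  }
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(acc_seg = x$acc_seg, acc_fruit = x$acc_fruit,
             seg_over = x$seg_over, seg_under = x$seg_under,
             k_matching = x$k_matching, m = x$m, n = x$n,
             l_fruit = x$l_fruit, a = x$a,
             p_gt = x$p_gt, p_over = x$p_over, p_under = x$p_under)
}
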