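#' Evaluate a predicted segmentation against ground truth
#'
#' Matches predicted classes to truth classes by majority overlap
#' (confusion cells taken in decreasing order, ties resolved toward lower
#' truth then lower predicted index — deterministic and invariant to
#' renumbering of the prediction), then reports per-class Dice and Jaccard
#' overlap, overall pixel accuracy, the full confusion matrix, and — when
#' reference cuts are supplied — the absolute gray-level error of each
#' recovered threshold.  Classes with no truth pixels score Dice 0 and are
#' flagged rather than dropped.  `NA` predicted labels count as wrong for
#' every class.
#'
#' @param pred Predicted [label_map()].
#' @param truth Ground-truth [label_map()].
#' @param reference_cuts Optional [threshold_vector()] (or integer vector)
#'   of reference cuts to score threshold recovery; compared against
#'   `pred_cuts`.
#' @param pred_cuts Optional cuts that produced `pred` (needed with
#'   `reference_cuts`).
#' @return Object of class `eval_report`: `per_class_dice`,
#'   `per_class_jaccard`, `overall_accuracy`, `confusion` (truth rows,
#'   matched-prediction columns), `matching` (pred -> truth), `flags`,
#'   `threshold_error`.
#' @examples
#' t <- label_map(matrix(c(0L, 0L, 1L, 1L), 2, 2), 2)
#' evaluate_segmentation(t, t)$overall_accuracy  # 1
#' @export
evaluate_segmentation <- function(pred, truth, reference_cuts = NULL,
                                  pred_cuts = NULL) {
  if (!is_label_map(pred) || !is_label_map(truth)) {
    abort_domain("`pred` and `truth` must be label_map objects")
  }
  if (!identical(dim(pred$labels), dim(truth$labels))) {
    abort_domain("`pred` and `truth` must have the same shape")
  }
  K <- max(pred$n_classes, truth$n_classes)
  lv <- 0:(K - 1)
  conf_raw <- table(
    truth = factor(truth$labels, levels = lv),
    pred = factor(pred$labels, levels = lv)
  )
  conf_raw <- unclass(conf_raw)

  # Majority-overlap matching: greedily pair the largest confusion cells.
  ord <- order(-as.vector(conf_raw), rep(lv, times = K), rep(lv, each = K))
  map <- rep(NA_integer_, K)      # pred class -> truth class
  truth_taken <- logical(K)
  for (idx in ord) {
    ti <- ((idx - 1) %% K) + 1
    pi <- ((idx - 1) %/% K) + 1
    if (is.na(map[pi]) && !truth_taken[ti]) {
      map[pi] <- ti
      truth_taken[ti] <- TRUE
    }
  }
  leftover <- which(!truth_taken)
  map[is.na(map)] <- leftover

  conf <- conf_raw[, order(map), drop = FALSE]
  colnames(conf) <- rownames(conf)

  n <- length(truth$labels)
  tp <- diag(conf)
  truth_n <- rowSums(conf)
  pred_n <- colSums(conf)
  denom_d <- truth_n + pred_n
  dice <- ifelse(denom_d > 0, 2 * tp / denom_d, 1)
  union_n <- denom_d - tp
  jaccard <- ifelse(union_n > 0, tp / union_n, 1)
  flags <- unname(ifelse(truth_n == 0, "absent-from-truth", ""))

  te <- NULL
  if (!is.null(reference_cuts)) {
    if (is.null(pred_cuts)) {
      abort_domain("`pred_cuts` must be given with `reference_cuts`")
    }
    rc <- if (is_threshold_vector(reference_cuts)) reference_cuts$cuts else as.integer(reference_cuts)
    pc <- if (is_threshold_vector(pred_cuts)) pred_cuts$cuts else as.integer(pred_cuts)
    if (length(rc) != length(pc)) {
      abort_domain("reference and predicted cut vectors differ in length")
    }
    te <- abs(pc - rc)
  }

  # NA predictions fall outside every matched column, so accuracy from the
  # confusion diagonal already counts them as errors.
  structure(
    list(
      per_class_dice = as.numeric(dice),
      per_class_jaccard = as.numeric(jaccard),
      overall_accuracy = sum(tp) / n,
      confusion = conf,
      matching = map - 1L,
      flags = flags,
      threshold_error = te
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  accuracy: %.4f\n", x$overall_accuracy))
  cat(sprintf(
    "  dice:     %s\n", paste(sprintf("%.4f", x$per_class_dice), collapse = " ")
  ))
  cat(sprintf(
    "  jaccard:  %s\n", paste(sprintf("%.4f", x$per_class_jaccard), collapse = " ")
  ))
  if (!is.null(x$threshold_error)) {
    cat(sprintf(
      "  |cut error|: %s\n", paste(x$threshold_error, collapse = " ")
    ))
  }
  invisible(x)
}

#' Flatten an evaluation report to one data-frame row
#'
#' Convenience for batch sweeps: one row with accuracy, per-class Dice and
#' Jaccard, and per-cut threshold errors.
#'
#' @param report An `eval_report`.
#' @return One-row `data.frame`.
#' @export
eval_report_row <- function(report) {
  out <- data.frame(overall_accuracy = report$overall_accuracy)
  for (i in seq_along(report$per_class_dice)) {
    out[[paste0("dice_", i - 1)]] <- report$per_class_dice[i]
    out[[paste0("jaccard_", i - 1)]] <- report$per_class_jaccard[i]
  }
  for (i in seq_along(report$threshold_error)) {
    out[[paste0("cut_err_", i)]] <- report$threshold_error[i]
  }
  out
}
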